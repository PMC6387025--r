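## Independent brute-force oracles. These deliberately share no code with the
## implementations they check: they are direct, slow transcriptions of the
## smoothing and labeling rules.

## Binary-sequence smoothing, transcribed literally: find the most frequent
## 1-run length M1 (ties -> larger); 1-runs shorter than M1/2 are candidates,
## the rest confirmed; M0 likewise over 0-runs; a candidate survives only if
## no confirmed run starts strictly closer than M0/2 (start-to-start).
oracle_smooth_binary <- function(bits) {
  bits <- as.integer(bits)
  n <- length(bits)
  runs <- list(); i <- 1
  while (i <= n) {
    j <- i
    while (j < n && bits[j + 1] == bits[i]) j <- j + 1
    runs[[length(runs) + 1]] <- c(value = bits[i], start = i - 1,
                                  len = j - i + 1)
    i <- j + 1
  }
  lens1 <- sapply(Filter(function(r) r["value"] == 1, runs), `[`, "len")
  if (!length(lens1)) return(bits)
  freq <- table(lens1)
  M1 <- max(as.integer(names(freq)[freq == max(freq)]))
  lens0 <- sapply(Filter(function(r) r["value"] == 0, runs), `[`, "len")
  M0 <- if (length(lens0)) {
    f0 <- table(lens0)
    max(as.integer(names(f0)[f0 == max(f0)]))
  } else NA
  ones <- Filter(function(r) r["value"] == 1, runs)
  conf <- sapply(ones, function(r) r["len"] >= M1 / 2)
  if (!any(conf)) conf[which.max(sapply(ones, `[`, "len"))] <- TRUE
  if (is.na(M0)) return(bits)
  conf_starts <- sapply(ones[conf], `[`, "start")
  out <- bits
  for (r in ones[!conf]) {
    if (any(abs(conf_starts - r["start"]) < M0 / 2)) {
      out[(r["start"] + 1):(r["start"] + r["len"])] <- 0L
    }
  }
  out
}

## Label smoothing, transcribed literally as a fixpoint of: any maximal run
## of Ek (k != null) strictly shorter than t_min[Ek], whose two neighbouring
## runs carry the same label Ej != Ek, becomes Ej. Shortest run first.
oracle_smooth_labels <- function(labels, t_min, resolution) {
  repeat {
    n <- length(labels)
    ## explicit run scan
    run_start <- c(1, which(labels[-1] != labels[-n]) + 1)
    run_end <- c(run_start[-1] - 1, n)
    changed <- FALSE
    if (length(run_start) >= 3) {
      ord <- order(run_end - run_start)
      for (ri in ord) {
        if (ri == 1 || ri == length(run_start)) next
        lab <- labels[run_start[ri]]
        if (lab == "null") next
        left <- labels[run_start[ri - 1]]
        right <- labels[run_start[ri + 1]]
        dur <- (run_end[ri] - run_start[ri] + 1) * resolution
        if (left == right && left != lab && dur < t_min[lab] - 1e-12) {
          labels[run_start[ri]:run_end[ri]] <- left
          changed <- TRUE
          break
        }
      }
    }
    if (!changed) return(labels)
  }
}

## brute-force per-step majority vote
oracle_majority_vote <- function(starts, labels, W, seq_len, classes) {
  out <- character(seq_len)
  for (t in seq_len(seq_len)) {
    cover <- which(starts < t & t <= starts + W)
    if (length(cover)) {
      cnt <- table(factor(labels[cover], classes))
      out[t] <- classes[which.max(cnt)]
    } else {
      out[t] <- NA_character_
    }
  }
  ## nearest covered step, ties to the earlier side
  cov <- which(!is.na(out))
  for (t in which(is.na(out))) {
    d <- abs(cov - t)
    out[t] <- out[cov[order(d, cov)][1]]
  }
  out
}

## brute-force containment scan for counting labels
oracle_counting_bits <- function(starts, W, v_samples, half) {
  vapply(starts, function(a) {
    as.integer(any(v_samples >= a & v_samples + half <= a + W))
  }, integer(1))
}
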