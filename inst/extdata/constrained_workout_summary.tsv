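exercise	code	participants	time_min	repetitions	fraction_of_time
Push-up	E1	50	25.05	718	0.11
Pull-up	E2	43	13.63	300	0.06
Burpee	E3	47	30.97	551	0.13
Kettlebell deadlift	E4	48	28.43	689	0.12
Box jump	E5	47	19.2	546	0.08
Air squat	E6	44	22.27	642	0.10
Sit-up	E7	42	26.5	555	0.12
Wall ball	E8	42	23.42	529	0.10
Kettlebell press	E9	44	19.7	482	0.09
Kettlebell thruster	E10	39	20.88	449	0.09
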