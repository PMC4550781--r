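species	ploidy	non_pct	total_pct	full_pct	hemi_pct
C. boreale	2	47.1	52.9	27.5	25.4
C. dichrum	2	47.8	52.2	26.9	25.3
C. japonicum	2	45.4	54.6	27.5	27.1
C. lavandulifolium	2	50.2	49.8	25.4	24.4
C. nankingense	2	46.8	53.2	27.5	25.7
T. vulgare	2	48.1	51.9	26.0	26.0
C. chanetii	4	44.5	55.5	30.2	25.3
C. indicum	4	47.6	52.4	26.3	26.1
C. japonicum var. wakasaense	4	45.9	54.1	28.2	25.9
C. okiense	4	45.6	54.4	28.5	25.9
C. yoshinaganthum	4	46.7	53.3	26.8	26.5
C. japonense	6	44.4	55.6	28.4	27.2
C. morifolium	6	47.5	52.5	25.0	27.5
C. vestitum	6	45.2	54.8	28.8	26.0
C. zawadskii	6	45.4	54.6	30.0	24.5
A. x marginatum	8	43.4	56.6	28.1	28.5
A. shiwogiku	8	43.3	56.7	28.4	28.3
C. ornatum	8	42.9	57.1	30.0	27.0
C. crassum	10	44.1	55.9	28.1	27.8
A. pacificum	10	40.8	59.2	30.5	28.8
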