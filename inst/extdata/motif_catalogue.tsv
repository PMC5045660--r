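name	pattern	annotation
SORLIP2AT	GGGCC	light-responsive, phyA-induced transcripts
SITEIIATCYTC	TGGGCY	PCNA gene regulation, site II element
UP1ATMSD	GGCCCAWWW	up-regulated in axillary buds
TBF1HSF	GAAGAAGAA	defence response, thermotolerance
ACGTABREMOTIFA2OSEM	ACGTGKC	ABA-responsive element, drought
BOXIIPCCHS	ACGTGGC	light-responsive box II
CACGTGMOTIF	CACGTG	G-box, abiotic stress
CAMTA1	CCGCGT	calmodulin-binding transcription activator site
ABRERATCAL	MACGYGB	ABA-responsive, calcium signalling
TATABOX2	TATAAAT	core promoter TATA box
TATABOX3	TATTAAT	core promoter TATA box variant
TATABOX4	TATATAA	core promoter TATA box variant
CAATBOX1	CCAAT	CAAT box, core promoter
GATABOX	GATA	light regulation, tissue specificity
IBOXCORE	GATAA	I-box, light-regulated genes
GT1CONSENSUS	GRWAAW	GT-1 binding, light and stress
WBOXNTERF3	TGACY	W-box, WRKY binding, wounding
WRKY71OS	TGAC	WRKY71 binding, defence
MYBCORE	CNGTTR	MYB binding, drought and flavonoids
MYCCONSENSUSAT	CANNTG	MYC binding, dehydration and cold
EBOXBNNAPA	CANNTG	E-box, seed storage genes
DRECRTCOREAT	RCCGAC	dehydration-responsive element core
LTRECOREATCOR15	CCGAC	low-temperature-responsive element
GCCCORE	GCCGCC	ethylene-responsive GCC box
ERELEE4	AWTTCAAA	ethylene-responsive element
ARR1AT	NGATT	cytokinin response regulator binding
DOFCOREZM	AAAG	Dof protein binding core
POLLEN1LELAT52	AGAAA	pollen-specific expression
ROOTMOTIFTAPOX1	ATATT	root-specific expression
CURECORECR	GTAC	copper-responsive element core
GAGAGMGSA1	GAGAGAGAGAGAGAGAG	GAGA element, gibberellin response
PYRIMIDINEBOXOSRAMY1A	CCTTTT	gibberellin-responsive pyrimidine box
AMYBOX1	TAACARA	alpha-amylase promoter element
CGCGBOXAT	VCGCGB	calmodulin-binding, stress signalling
PREATPRODH	ACTCAT	proline dehydrogenase induction
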