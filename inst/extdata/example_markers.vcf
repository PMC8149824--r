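##fileformat=VCFv4.2
##source=freeBayes v1.3.1
##INFO=<ID=AO,Number=A,Type=Integer,Description="Alternate allele observation count">
##INFO=<ID=SAF,Number=A,Type=Integer,Description="Alternate observations on the forward strand">
##INFO=<ID=SAR,Number=A,Type=Integer,Description="Alternate observations on the reverse strand">
##INFO=<ID=RPR,Number=A,Type=Float,Description="Reads placed right of the alternate allele">
##INFO=<ID=RPL,Number=A,Type=Float,Description="Reads placed left of the alternate allele">
##INFO=<ID=MQM,Number=A,Type=Float,Description="Mean mapping quality of alternate observations">
##INFO=<ID=MQMR,Number=1,Type=Float,Description="Mean mapping quality of reference observations">
##INFO=<ID=TYPE,Number=A,Type=String,Description="Allele type">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
chrI	500	.	A	G	50	.	AO=4;SAF=5;SAR=6;RPR=3;RPL=4;MQM=60;MQMR=60;TYPE=snp
chrI	800	.	C	T	80	.	AO=6;SAF=0;SAR=6;RPR=3;RPL=4;MQM=60;MQMR=60;TYPE=snp
chrI	1000	.	G	A	0.5	.	AO=2;SAF=1;SAR=1;RPR=2;RPL=2;MQM=60;MQMR=60;TYPE=snp
chrI	1200	.	T	C	100	.	AO=50;SAF=25;SAR=25;RPR=20;RPL=30;MQM=60;MQMR=60;TYPE=snp
chrI	1400	.	A	C	60	.	AO=5;SAF=3;SAR=2;RPR=1;RPL=4;MQM=60;MQMR=60;TYPE=snp
chrI	1600	.	G	T	60	.	AO=5;SAF=3;SAR=2;RPR=3;RPL=2;MQM=51;MQMR=60;TYPE=snp
chrI	1800	.	C	G	60	.	AO=5;SAF=3;SAR=2;RPR=3;RPL=2;MQM=66;MQMR=60;TYPE=snp
chrI	1950	.	T	A	70	.	AO=5;SAF=3;SAR=2;RPR=3;RPL=2;MQM=60;MQMR=60;TYPE=snp
chrI	2200	.	AT	A	90	.	AO=6;SAF=3;SAR=3;RPR=3;RPL=3;MQM=60;MQMR=60;TYPE=del
chrI	2400	.	G	A,C	90	.	AO=4,3;SAF=2,2;SAR=2,1;RPR=2,2;RPL=2,1;MQM=60,60;MQMR=60;TYPE=snp,snp
chrI	2600	.	A	T	75	.	AO=5;SAF=3;SAR=2;RPR=3;RPL=2;MQM=60;TYPE=snp
chrII	300	.	C	A	55	.	AO=4;SAF=2;SAR=2;RPR=2;RPL=2;MQM=59;MQMR=60;TYPE=snp
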