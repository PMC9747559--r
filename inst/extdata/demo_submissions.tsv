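variant_key	submitter_id	classification	assertion_criteria_met	submission_date
CFTR:c.1521_1523delCTT	lab01	P	TRUE	2019-03-14
CFTR:c.1521_1523delCTT	lab02	P	TRUE	2020-01-08
CFTR:c.1521_1523delCTT	ext01	P	TRUE	2020-02-02
SMN1:c.770_780dup	lab01	LP	TRUE	2018-11-30
SMN1:c.770_780dup	lab03	P	TRUE	2019-06-21
HEXA:c.1274_1277dupTATC	lab02	P	TRUE	2020-12-01
HEXA:c.1274_1277dupTATC	lab03	P	TRUE	2019-09-09
GJB2:c.101T>C	lab01	VUS	TRUE	2019-05-05
GJB2:c.101T>C	lab02	LP	TRUE	2019-10-17
PAH:c.1222C>T	lab03	P	FALSE	2019-12-25
PAH:c.1222C>T	lab01	P	TRUE	2020-04-19
MEFV:c.2080A>G	lab02	LB	TRUE	2019-08-13
MEFV:c.2080A>G	lab03	B	TRUE	2020-03-03
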