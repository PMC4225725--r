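# Starter family rule table.
# Columns: family, category, must_have, prohibited ("-" = none).
# Logic language: & = AND, | = OR, parentheses group; & binds tighter than |.
# The ARF and MADS logics follow the published family characterizations
# (ARF needs the B3 DNA-binding domain plus one of the two ARF-specific
# domains; the K-box splits the MADS superfamily). The B3 / AP2-EREBP /
# RAV triangle and the BTB/POZ split (MATH vs ankyrin companion domain)
# are scaffold entries: domain choices are curator's best effort and
# should be reviewed before production use.
family	category	must_have	prohibited
ARF	TF	(IPR010525|IPR011525)&IPR003340	-
MADS type1	TF	IPR002100	IPR002487
MADS-MICK	TF	IPR002100&IPR002487	-
B3	TF	IPR003340	IPR001471|IPR010525|IPR011525
AP2-EREBP	TF	IPR001471	IPR003340
RAV	TF	IPR003340&IPR001471	IPR010525|IPR011525
BTB-POZ-MATH	TR	(PS50097|SM00225)&IPR002083	-
ABTB	TR	(PS50097|SM00225)&IPR002110	-
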