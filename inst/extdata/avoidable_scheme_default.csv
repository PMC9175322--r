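# Default avoidability rule table (synthetic working default).
# Ordered ICD-10 code ranges; first match wins; ages >= the cap are always
# non_avoidable. Covers the major OECD/Eurostat avoidable-mortality cause
# families; replace with a full published rule list for production use.
range_start,range_end,category
I20,I25,ihd
A00,A09,treatable
A15,A19,treatable_and_preventable
A33,A37,preventable
A39,A41,treatable
B15,B19,preventable
B20,B24,preventable
C18,C21,treatable
C33,C34,preventable
C43,C44,preventable
C50,C50,treatable
C53,C55,treatable
C62,C62,treatable
C81,C81,treatable
E10,E14,treatable_and_preventable
F10,F16,preventable
F18,F19,preventable
G40,G41,treatable
I10,I15,treatable_and_preventable
I60,I69,treatable_and_preventable
J09,J11,preventable
J12,J18,treatable
J20,J22,treatable
J40,J47,preventable
K25,K27,treatable
K35,K38,treatable
K80,K81,treatable
N00,N07,treatable
O00,O99,treatable
P00,P96,treatable
Q20,Q28,treatable
V01,X59,preventable
X60,X84,preventable
X85,Y09,preventable
Y10,Y89,preventable
A00,Z99,non_avoidable
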