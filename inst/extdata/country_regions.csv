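country_code,region
AD,Europe
AE,Asia
AF,Asia
AL,Europe
AM,Asia
AO,Africa
AR,South America
AT,Europe
AU,Oceania
AZ,Asia
BA,Europe
BD,Asia
BE,Europe
BF,Africa
BG,Europe
BH,Asia
BJ,Africa
BO,South America
BR,South America
BW,Africa
BY,Europe
CA,North America
CD,Africa
CH,Europe
CI,Africa
CL,South America
CM,Africa
CN,Asia
CO,South America
CR,North America
CU,North America
CY,Europe
CZ,Europe
DE,Europe
DK,Europe
DO,North America
DZ,Africa
EC,South America
EE,Europe
EG,Africa
ES,Europe
ET,Africa
FI,Europe
FJ,Oceania
FR,Europe
GB,Europe
GE,Asia
GH,Africa
GR,Europe
GT,North America
HK,Asia
HN,North America
HR,Europe
HT,North America
HU,Europe
ID,Asia
IE,Europe
IL,Asia
IN,Asia
IQ,Asia
IR,Asia
IS,Europe
IT,Europe
JM,North America
JO,Asia
JP,Asia
KE,Africa
KH,Asia
KR,Asia
KW,Asia
KZ,Asia
LB,Asia
LK,Asia
LT,Europe
LU,Europe
LV,Europe
LY,Africa
MA,Africa
MD,Europe
ME,Europe
MG,Africa
MK,Europe
ML,Africa
MM,Asia
MN,Asia
MT,Europe
MU,Africa
MX,North America
MY,Asia
MZ,Africa
NA,Africa
NG,Africa
NI,North America
NL,Europe
NO,Europe
NP,Asia
NZ,Oceania
OM,Asia
PA,North America
PE,South America
PG,Oceania
PH,Asia
PK,Asia
PL,Europe
PR,North America
PT,Europe
PY,South America
QA,Asia
RO,Europe
RS,Europe
RU,Europe
RW,Africa
SA,Asia
SD,Africa
SE,Europe
SG,Asia
SI,Europe
SK,Europe
SN,Africa
SO,Africa
SV,North America
SY,Asia
TH,Asia
TN,Africa
TR,Asia
TT,North America
TW,Asia
TZ,Africa
UA,Europe
UG,Africa
US,North America
UY,South America
UZ,Asia
VE,South America
VN,Asia
YE,Asia
ZA,Africa
ZM,Africa
ZW,Africa
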