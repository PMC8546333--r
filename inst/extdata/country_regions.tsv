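country	region
US	North America
CA	North America
MX	North America
GT	North America
BZ	North America
SV	North America
HN	North America
NI	North America
CR	North America
PA	North America
CU	North America
DO	North America
HT	North America
JM	North America
TT	North America
BS	North America
BB	North America
AG	North America
DM	North America
GD	North America
KN	North America
LC	North America
VC	North America
PR	North America
BM	North America
GL	North America
BR	South America
AR	South America
CL	South America
CO	South America
PE	South America
VE	South America
EC	South America
BO	South America
PY	South America
UY	South America
GY	South America
SR	South America
GF	South America
FK	South America
GB	Europe
DE	Europe
FR	Europe
IT	Europe
ES	Europe
PT	Europe
NL	Europe
BE	Europe
LU	Europe
IE	Europe
DK	Europe
SE	Europe
NO	Europe
FI	Europe
IS	Europe
AT	Europe
CH	Europe
PL	Europe
CZ	Europe
SK	Europe
HU	Europe
RO	Europe
BG	Europe
GR	Europe
HR	Europe
SI	Europe
RS	Europe
BA	Europe
ME	Europe
MK	Europe
AL	Europe
EE	Europe
LV	Europe
LT	Europe
UA	Europe
BY	Europe
MD	Europe
RU	Europe
MT	Europe
CY	Europe
LI	Europe
MC	Europe
SM	Europe
AD	Europe
VA	Europe
XK	Europe
JP	Asia
CN	Asia
KR	Asia
KP	Asia
IN	Asia
PK	Asia
BD	Asia
LK	Asia
NP	Asia
BT	Asia
MV	Asia
MM	Asia
TH	Asia
VN	Asia
LA	Asia
KH	Asia
MY	Asia
SG	Asia
ID	Asia
PH	Asia
BN	Asia
TL	Asia
MN	Asia
TW	Asia
HK	Asia
MO	Asia
KZ	Asia
KG	Asia
TJ	Asia
TM	Asia
UZ	Asia
AF	Asia
IR	Asia
IQ	Asia
SY	Asia
LB	Asia
IL	Asia
PS	Asia
JO	Asia
SA	Asia
YE	Asia
OM	Asia
AE	Asia
QA	Asia
BH	Asia
KW	Asia
TR	Asia
GE	Asia
AM	Asia
AZ	Asia
AU	Oceania
NZ	Oceania
PG	Oceania
FJ	Oceania
SB	Oceania
VU	Oceania
WS	Oceania
TO	Oceania
TV	Oceania
KI	Oceania
NR	Oceania
PW	Oceania
FM	Oceania
MH	Oceania
NC	Oceania
PF	Oceania
GU	Oceania
ZA	Africa
EG	Africa
NG	Africa
ET	Africa
KE	Africa
TZ	Africa
UG	Africa
DZ	Africa
MA	Africa
TN	Africa
LY	Africa
SD	Africa
SS	Africa
GH	Africa
CI	Africa
SN	Africa
ML	Africa
BF	Africa
NE	Africa
TD	Africa
CM	Africa
CF	Africa
CG	Africa
CD	Africa
GA	Africa
GQ	Africa
AO	Africa
ZM	Africa
ZW	Africa
MW	Africa
MZ	Africa
NA	Africa
BW	Africa
LS	Africa
SZ	Africa
MG	Africa
MU	Africa
SC	Africa
KM	Africa
DJ	Africa
SO	Africa
ER	Africa
RW	Africa
BI	Africa
TG	Africa
BJ	Africa
GN	Africa
GW	Africa
GM	Africa
SL	Africa
LR	Africa
MR	Africa
CV	Africa
ST	Africa
UNITED STATES	North America
UNITED STATES OF AMERICA	North America
USA	North America
CANADA	North America
MEXICO	North America
COSTA RICA	North America
PANAMA	North America
CUBA	North America
JAMAICA	North America
PUERTO RICO	North America
BRAZIL	South America
ARGENTINA	South America
CHILE	South America
COLOMBIA	South America
PERU	South America
VENEZUELA	South America
ECUADOR	South America
URUGUAY	South America
PARAGUAY	South America
BOLIVIA	South America
UNITED KINGDOM	Europe
GREAT BRITAIN	Europe
ENGLAND	Europe
GERMANY	Europe
FRANCE	Europe
ITALY	Europe
SPAIN	Europe
PORTUGAL	Europe
NETHERLANDS	Europe
BELGIUM	Europe
IRELAND	Europe
DENMARK	Europe
SWEDEN	Europe
NORWAY	Europe
FINLAND	Europe
AUSTRIA	Europe
SWITZERLAND	Europe
POLAND	Europe
CZECH REPUBLIC	Europe
HUNGARY	Europe
ROMANIA	Europe
GREECE	Europe
RUSSIA	Europe
RUSSIAN FEDERATION	Europe
UKRAINE	Europe
CROATIA	Europe
SERBIA	Europe
SLOVAKIA	Europe
SLOVENIA	Europe
BULGARIA	Europe
ESTONIA	Europe
LATVIA	Europe
LITHUANIA	Europe
ICELAND	Europe
LUXEMBOURG	Europe
MALTA	Europe
CYPRUS	Europe
TURKEY	Europe
JAPAN	Asia
CHINA	Asia
SOUTH KOREA	Asia
KOREA, REPUBLIC OF	Asia
REPUBLIC OF KOREA	Asia
INDIA	Asia
PAKISTAN	Asia
BANGLADESH	Asia
THAILAND	Asia
VIETNAM	Asia
VIET NAM	Asia
MALAYSIA	Asia
SINGAPORE	Asia
INDONESIA	Asia
PHILIPPINES	Asia
TAIWAN	Asia
HONG KONG	Asia
ISRAEL	Asia
SAUDI ARABIA	Asia
UNITED ARAB EMIRATES	Asia
IRAN	Asia
IRAQ	Asia
JORDAN	Asia
LEBANON	Asia
KUWAIT	Asia
QATAR	Asia
KAZAKHSTAN	Asia
AUSTRALIA	Oceania
NEW ZEALAND	Oceania
FIJI	Oceania
PAPUA NEW GUINEA	Oceania
SAMOA	Oceania
TONGA	Oceania
SOUTH AFRICA	Africa
EGYPT	Africa
NIGERIA	Africa
KENYA	Africa
ETHIOPIA	Africa
MOROCCO	Africa
ALGERIA	Africa
TUNISIA	Africa
GHANA	Africa
TANZANIA	Africa
UGANDA	Africa
ZIMBABWE	Africa
ZAMBIA	Africa
CAMEROON	Africa
SENEGAL	Africa
ANGOLA	Africa
MOZAMBIQUE	Africa
MADAGASCAR	Africa
MAURITIUS	Africa
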