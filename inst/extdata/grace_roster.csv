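id,sex,origin,estimated_age,status
AMA,F,Goma,14,Adult
ISA,F,Single,10,Adult
ITE,F,Kinigi,19,Adult
KAL,F,Single,9,Adult
KIG,M,Goma,14,Silverback
LUB,M,Single,13,Blackback
LUL,F,Single,7,Subadult
MAP,F,Goma,18,Adult
MUY,F,Single,11,Adult
NDJ,F,Goma,13,Adult
PIN,F,Kinigi,21,Adult
SER,F,Kinigi,20,Adult
SHA,M,Single,12,Blackback
TUM,F,Kinigi,16,Adult
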