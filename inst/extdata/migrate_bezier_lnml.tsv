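model	NE	MW	SW
EC no migration	-117680.5	-117668.1	-117668.1
EC migration	-117664.6	NA	NA
CC no migration	-117697.1	-117684.4	-117684.1
CC migration	-117665.7	-117667.5	-117666.2
WC no migration	-117667.9	-117710.0	-117696.6
WC migration	NA	-117666.6	-117666.2
NE no migration	NA	-117663.2	-117663.7
NE migration	NA	-117666.4	NA
MW no migration	-117687.2	NA	-117671.8
MW migration	-117665.2	NA	-117666.3
SW no migration	-117665.9	-117671.1	NA
SW migration	NA	-117666.4	NA
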