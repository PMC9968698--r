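name	formula	mode	id
L-tryptophan	C11H12N2O2	both	SYN0001
L-kynurenine	C10H12N2O3	both	SYN0002
TG(56:4)	C59H106O6	positive	SYN0003
D-glucose	C6H12O6	both	SYN0004
glutathione	C10H17N3O6S	both	SYN0005
L-leucine	C6H13NO2	both	SYN0006
L-isoleucine	C6H13NO2	both	SYN0007
palmitic acid	C16H32O2	negative	SYN0008
L-lactate	C3H6O3	negative	SYN0009
ATP	C10H16N5O13P3	both	SYN0010
Cer(d18:1/16:0)	C34H67NO3	positive	SYN0011
cholesterol	C27H46O	positive	SYN0012
taurine	C2H7NO3S	both	SYN0013
L-phenylalanine	C9H11NO2	both	SYN0014
citrate	C6H8O7	negative	SYN0015
L-carnitine	C7H15NO3	positive	SYN0016
creatinine	C4H7N3O	both	SYN0017
hypoxanthine	C5H4N4O	both	SYN0018
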