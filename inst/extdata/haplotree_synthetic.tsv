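name	parent	variants
MRCA		
M	MRCA	263G,750G,2706G,15326G,10400T,14783C,4221G,15154A,10851T,11678T,15143A,11434T,6370C,3889A
N	MRCA	5862G,11829A,7046T,11840G,3103C,11604A,9862T,15221C,8357T,10345T,4870T,1315C,6628C,3216C
R	N	10443T,14008G,8666A,9390T,7552A,4769A,7669C,12714G,14914A,4660G,14333C,5277G,1589C,3100T
H	R	705C,6260A,5804T,6876A,5585G,2810G,5135C,2388T,4757C,16481G,10331C,11114C,5075T,11939C
U	R	5472A,717T,14646C,9131C,10325G,12580G,6988T,4124A,12589A,15615T,6716C,8644T,3425C,14519G
J	R	15452A,288A,7849C,7384G,11154C,3073A,8546T,8172G,1384T,14428A,3257A,5866T,3399G,14862T
T	R	10748G,6874T,5000C,1003A,10876T,1070G,7666C,2007A,16155T,6662T,4157G,10496A,10060G,2296G
K	R	15856C,12452C,9393A,2152A,13568A,12099C,6480G,4230T,9757T,7714T,10101A,1408T,9613T,4010G
B	R	13081A,13558G,5910G,9633C,5475G,15697A,16258A,10308T,3485C,13744C,5148T,6385C,9865A,7214A
C	M	15301A,3655T,9121C,12509C,7901C,13749G,7267A,3446T,1343G,3192C,12611T,6359T,5448T,2155A
D	M	489C,16207C,11852T,5159A,12210A,10750G,7796T,7847C,7855C,11564A,2520G,7644T,12742G,11454T
M7	M	13870C,1879G,4658G,11238C,15488T,3127C,1749G,9898C,3565T,10436G,8369G,13859C
W	N	4526G,12549A,2404T,8607A,2545C,9765A,13152T,359C,5708G,6851G,553G,11512T,12595C,7894C
I	N	1529A,4070G,2771A,11115C,1481T,10301C,3717T,1366A,12752C,15039C,10167T,12366A,1281T,44G
N1a	N	5919G,3917T,7971C,6063G,1677C,5931A,10242C,9509G,10188G,12723A,8095G,1208A,11050G,10315A,8563T,3205C,5598T,11170C,8890G,11552C,3218G,11201G,3824C,10300G,10576G,14221T,3736C,9716T
H1	H	1818T,3952T,14953C,2989G,4706C,16502A,767A,11476T,14155C,2206G,13261G,12470C
H2	H	12878G,785T,12395T,4907G,2039C,5177A,4456T,3547G,15794G,3115C,4728C,7859C
H1c4b	H1	14223T,13439G,914A,7445C,8755G,13813T,14799G,16537T,6998G,13590G
H1a	H1	6556C,9974T,13745T,9505C,8547A,4676G,13143T,13862T,3790G,2098C
H2a1c	H2	14453A,2638A,3716G,1789A,12914C,8578C,6110T,14823T,112C,1817A
U5	U	11882C,6817A,7705T,1300G,11331A,3791A,9119T,9477C,14806T,579T,1035T,3256A
U4	U	56C,1060T,14603G,14632T,2347G,1116G,7258C,15131G,7278C,6836G,308G,3550T
U5a	U5	1294A,13936A,2131G,3539A,15705G,13996G,12411G,2605T,3750C,1052A
J1	J	6052G,11955T,15147A,725C,9403A,6080G,8063T,13769C,15092A,4387T,2326T,1711C
J2	J	8503C,7448T,16311C,4109G,3560A,6691A,4674G,1700C,15875G,5310T,11811T,9163G
J1c2	J1	12118G,2926A,9149A,6060A,282C,10240G,4216T,14578G,2263G,15612A
T2	T	13194T,3898C,11588C,11854A,10484C,5972A,956A,8469C,497A,6183A,13772A,10989T
T2b	T2	7707G,12630G,6755G,15810T,3863C,3523G,6155G,4461T,5697G,7646C
K1	K	4317C,15704C,4599G,1120T,6040T,5841C,3200G,12966G,7809G,10207G,3054A,14220A
K1a	K1	4400A,2975G,7421C,15563A,3676C,7977G,13955A,15048G,252T,7137T
B4	B	6051G,6806G,2451A,8176T,13933C,8548C,2036T,3804A,14886G,13915G,6098T,8214A
B4a	B4	12439C,13124A,3634C,2514G,3803G,8203T,4778T,7551G,10334T,9941G
C4	C	10646G,8297A,4790A,4331G,11174G,455T,14678A,2482G,9345G,10951G,11487C,1806C
C5	C	114A,5918G,15993G,15742A,2658C,11318C,15219A,2457G,6235A,6047A,7176C,13946T,6270G,10844C
C4a	C4	7013A,14244C,7326T,8513T,15129A,10659C,8076C,360A,4112T,711A
C4b	C4	7737C,7689A,3396A,4923A,5954C,4357C,2730G,4582C,4228G,9266C
D4	D	1123A,1211T,9176T,345T,4028G,10099C,14707G,6855C,8170A,15486A,13968A,326C
D2	D	881G,5037A,118T,6939G,14774G,13622A,3380C,13092G,12497G,16384G,12826A,3778G
D4i2a1	D4	15625T,7314A,6586A,3077A,8654C,4622A,9319G,29G,610G,10782G
D2a	D2	6320T,1083A,16216G,15643G,7063C,494A,13222G,2653G,4329A,14132A
M7a	M7	4384A,3101A,12725C,4516T,7696G,9495A,3573G,14165A,7315T,3823G,15963G,8327A,1744T,16378C,9426A,6915C
W1	W	3439C,4088T,2688T,6478T,3967A,10962C,421C,9712T,14526C,13383C,2057G,9105T,11277T,92C
I1	I	11491T,9258A,2004C,13524G,2651T,10426T,1463C,7120A,9205T,3884G,2981A,12737G,8441A,7135A
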