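IS01	IS01	IS01_fa	IS01_mo	1	2
IS01	IS01_fa	0	0	1	1
IS01	IS01_mo	0	0	2	1
IS02	IS02	IS02_fa	IS02_mo	2	2
IS02	IS02_fa	0	0	1	1
IS02	IS02_mo	0	0	2	1
IS03	IS03	IS03_fa	IS03_mo	1	2
IS03	IS03_fa	0	0	1	1
IS03	IS03_mo	0	0	2	1
IS04	IS04	IS04_fa	IS04_mo	2	2
IS04	IS04_fa	0	0	1	1
IS04	IS04_mo	0	0	2	1
IS05	IS05	IS05_fa	IS05_mo	2	2
IS05	IS05_fa	0	0	1	1
IS05	IS05_mo	0	0	2	1
IS06	IS06	IS06_fa	IS06_mo	1	2
IS06	IS06_fa	0	0	1	1
IS06	IS06_mo	0	0	2	1
IS07	IS07	0	0	2	2
IS08	IS08	0	0	1	2
IS09	IS09	0	0	2	2
IS10	IS10	0	0	1	2
IS11	IS11	0	0	2	2
IS12	IS12	0	0	1	2
IS13	IS13	0	0	2	2
IS14	IS14	0	0	1	2
IS15	IS15	0	0	2	2
IS16	IS16	0	0	1	2
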