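# Multi-channel ion-channel screening panel: pIC50 values (-log10 of IC50 in molar)
# for 34 marketed compounds that have had a Thorough QT study.
# Channels/screens: hERG (IKr), CaV1.2 (ICaL), NaV1.5 (INa), KCNQ1/MinK (IKs), Kv4.3/KChIP2.2 (Ito).
# Sources: Q = IonWorks Quattro screen; B = IonWorks Barracuda screen (26 compounds);
# Q2 = second independent Quattro screen; M = manual patch clamp (GLP regulatory submissions).
# A 0.0 entry means a pIC50 <= 0 was fitted (floored; IC50 > 1e6 uM, at most 0.01% block at 100 uM).
# Empty cells mean the compound was not screened on that platform.
display_name,herg_q,herg_b,herg_m,cav12_q,cav12_b,nav15_q,nav15_q2,kcnq1_q,kcnq1_q2,kv43_q
Alfuzosin,4.7,4.9,3.9,3.7,0.0,3.7,2.8,3.9,0.0,3.0
Alvimopan,1.2,,3.1,5.3,,3.6,,4.3,,0.0
Ambrisentan,2.1,0.0,3.3,2.6,0.0,2.9,3.0,3.3,4.2,3.6
Darifenacin,5.8,,7.1,2.8,,5.8,,4.7,,4.9
Darunavir,4.2,4.0,3.8,0.0,2.8,4.4,4.0,3.5,4.3,4.0
Dasatinib,4.3,4.3,4.8,3.4,3.6,4.0,3.4,3.6,0.0,3.5
Deferasirox,0.0,0.0,2.4,3.0,0.0,4.1,3.3,0.0,0.0,4.3
Desvenlafaxine,1.7,0.0,3.6,0.0,0.0,3.7,3.5,0.0,0.0,2.3
Dofetilide,6.9,6.2,8.0,3.8,0.0,3.5,3.2,3.6,3.8,0.0
Doripenem,2.1,,2.3,5.7,,2.8,,3.5,,0.0
Duloxetine,5.0,5.2,5.3,4.0,4.6,5.1,4.8,5.0,0.0,4.0
Eltrombopag,0.0,2.8,6.2,0.0,0.0,3.8,3.5,0.0,0.0,2.8
Etravirine,3.4,4.6,3.8,0.0,0.0,3.3,2.4,2.9,0.0,2.5
Everolimus,1.8,3.1,3.3,0.0,0.0,3.2,3.7,4.0,0.0,2.0
Lacosamide,0.0,,1.3,4.3,,3.3,,3.6,,0.0
Lamotrigine,3.4,3.6,3.6,2.8,2.9,4.0,4.4,3.8,0.0,0.0
Lapatinib,1.0,3.2,6.0,2.7,1.8,2.5,0.0,3.6,0.0,0.0
Maraviroc,3.9,4.1,4.4,0.0,0.0,3.0,3.2,4.2,0.0,0.0
Moxifloxacin,3.4,0.0,4.1,3.4,0.0,4.4,3.6,3.8,3.4,0.0
Nebivolol,5.2,5.2,6.5,0.0,4.8,5.2,5.1,4.8,4.4,4.3
Nelfinavir,1.5,3.3,4.9,0.0,0.0,4.1,3.3,4.1,0.0,2.3
Nilotinib,4.2,0.0,6.9,3.7,2.5,3.0,2.3,3.4,0.0,2.5
Paliperidone,6.0,5.9,5.9,3.4,3.0,4.6,3.8,3.6,0.0,4.2
Palonosetron,5.4,,5.7,3.4,,4.7,,4.3,,0.0
Raltegravir,2.5,3.5,2.8,0.0,0.0,3.5,2.8,4.6,0.0,2.3
Sildenafil,3.8,4.0,4.5,4.0,0.0,3.3,2.9,3.4,3.8,3.3
Silodosin,4.6,,5.1,3.1,,4.2,,3.6,,3.5
Sitagliptin,3.0,3.3,3.8,1.0,0.0,3.1,3.2,3.5,0.0,1.0
Solifenacin,5.8,,6.6,5.2,,5.2,,4.5,,4.3
Sunitinib,5.0,5.1,6.6,4.1,3.7,4.8,4.4,4.2,0.0,4.3
Tadalafil,4.1,3.9,4.0,0.0,3.4,3.9,3.8,3.8,3.6,0.0
Telbivudine,2.3,,0.8,0.0,,2.5,,3.6,,0.0
Tolterodine,6.9,6.8,7.9,0.0,4.6,5.2,4.5,4.1,0.0,4.9
Vardenafil,3.5,4.1,4.5,4.8,3.6,2.6,3.7,3.2,0.0,4.1
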