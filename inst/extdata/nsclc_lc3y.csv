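study_id,n_patients,n_fractions,total_dose,fraction_dose_isoc,fraction_dose_edge,bed10_isoc,bed10_edge,lc3y_pct,followup_months,flagged,notes
Kaskowitz 1993,53,35,62.971,1.79916,1.69968,74.3,69.6,51,NA,TRUE,"D=63 Gy (40-80), conventional, d and n not specified; n derived from D and BED"
Jeremic 1997,49,58,69.639,1.200667,1.099746,78,70.8,55,NA,FALSE,"D=69.6 Gy, d=1.2 Gy twice daily, T=40 d"
Hayakawa 1999,36,34,67.141,1.974744,1.874933,80.4,75.7,72,NA,TRUE,"D=60-81 Gy, d=2 Gy, T=48 d; n derived from BED at d~2 Gy; follow-up 36-216 m, median not given"
Cheung 2002,33,12,48,4,3.798674,67.2,62.9,63,23,FALSE,"D=48 Gy, d=4 Gy, T=21 d"
Langendijk 2002,46,35,70,2,1.899275,84,79.1,50,36,FALSE,"D=70 Gy, d=2 Gy, T=49 d"
Bradley 2003,56,35,69.786,1.993875,1.888914,83.7,78.6,63,20,TRUE,"D=60-84 Gy, d=1.8-2 Gy, T=42-56 d; n derived from BED at d~2 Gy"
Bogart 2005,31,28,70,2.5,2.399324,87.5,83.3,83,29,FALSE,"D=70 Gy, d=2.3-3.7 Gy, T=39 d; 28 x 2.5 Gy reproduces BED exactly"
Zehentmayr 2015,40,44,79.232,1.800735,1.699729,93.5,87.5,91,28.5,FALSE,"D=79.2 Gy (73.8-90), d=1.8 Gy twice daily, T=30-42 d"
Onimaru 2003,25,8,48,6,4.797959,76.8,56.8,55,18,FALSE,"D=48/60 Gy in 6/7.5 Gy fractions, T=14 d; BED matches 8 x 6 Gy at isocenter"
Xia 2006,25,10,100,10,5,200,75,96,27,TRUE,"GammaKnife, 50 Gy in 10 x 5 Gy at 50% isodose; printed dose fields garbled, BED read as 200/75 (10 x 10 Gy isocenter / 10 x 5 Gy edge)"
Fritz 2008,40,1,30,30,24,120,81.6,81,20,FALSE,D=30 Gy single fraction
Onimaru 2008,41,4,48,12,9.603082,105.6,75.3,57,27,FALSE,"D=40/48 Gy in 10/12 Gy fractions, T=5 d; BED matches 4 x 12 Gy"
Baumann 2009,57,3,66,22,15,211.2,112.5,92,35,FALSE,"D=45 Gy in 3 x 15 Gy at PTV edge, T=5 d (4-15); isocenter 3 x 22 Gy"
Brown 2009,31,3,88.199,29.399612,20,347.5,180,86,28,TRUE,"CyberKnife, D=60-67.5 Gy in 3-5 fractions; n=3 consistent with edge BED (3 x 20 Gy)"
Fakiris 2009,70,3,82.504,27.501282,22,309.4,211.2,88,50,FALSE,D=60/66 Gy in 3 x 20/22 Gy at PTV edge
Kopek 2009,88,3,45,15,10.099669,112.5,60.9,89,44,TRUE,"D=45/67.5 Gy in 15/22.5 Gy fractions, T=5-8 d; isocenter BED matches 3 x 15 Gy"
Stephans 2009,56,5,70,14,10,168,100,97,20,FALSE,"D=50 Gy in 5 x 10 Gy at PTV edge, T=11 d (8-14); isocenter 5 x 14 Gy"
Baba 2010,124,4,48,12,9.603082,105.6,75.3,80,26,TRUE,"48/52 Gy in 4 x 12/13 Gy by stage; majority (T1, 48 Gy) schedule BED used"
Crabtree 2010,76,3,67.505,22.501515,18,219.4,151.2,89,19,FALSE,"D=54 Gy in 3 x 18 Gy at PTV edge, T=8-14 d; isocenter 3 x 22.5 Gy"
Timmerman 2010,55,3,78.899,26.299627,18,286.4,151.2,98,34,FALSE,"D=54 Gy in 3 x 18 Gy at PTV edge, T=14 d"
Videtic 2010,26,5,53.994,10.798734,10,112.3,100,94,31,FALSE,"D=50 Gy in 5 x 10 Gy at PTV edge, T=5 d"
Andratschke 2011,92,5,76.168,15.233635,8.921207,192.2,84.4,83,21,TRUE,"D=24-45 Gy in 3-5 fractions, T=5-12 d; n=5 consistent with edge BED (45 Gy in 5 fractions)"
Hamamoto 2012,128,4,48,12,10.803481,105.6,89.9,85,18,FALSE,"D=48/60 Gy, d=9.2-14 Gy, T=4-10 d; BED matches 4 x 12 Gy"
Lagerwaard 2012,177,5,75,15,12,187.5,132,93,32,FALSE,"D=60 Gy, schedules 12/20/7.5 Gy per fraction; BED matches 5 x 15 Gy isocenter / 5 x 12 Gy edge"
Shibamoto 2012 (<3 cm),124,4,48,12,9.603082,105.6,75.3,86,36,FALSE,"D=48 Gy in 4 x 12 Gy, T=9-21 d; tumours < 3 cm"
Shibamoto 2012 (>=3 cm),52,4,52,13,10.402922,119.6,84.9,73,36,FALSE,"D=52 Gy in 4 x 13 Gy, T=9-21 d; tumours >= 3 cm"
Shirata 2012 (48 Gy),126,4,48,12,10.803481,105.6,89.9,100,30,TRUE,"48 Gy in 4 x 12 Gy; subgroup patient counts garbled in source, reconstructed so study totals match the reported 2319"
Shirata 2012 (60 Gy),29,8,60,7.5,6.800424,105,91.4,82,30,TRUE,"60 Gy in 8 x 7.5 Gy; subgroup patient counts garbled in source, reconstructed so study totals match the reported 2319"
Takeda 2012 (40 Gy),27,5,50,10,8,100,72,72,21,FALSE,"D=40 Gy in 5 x 8 Gy at PTV edge, T=5 d; isocenter 5 x 10 Gy"
Takeda 2012 (50 Gy),138,5,62.493,12.498571,10,140.6,100,87,21,FALSE,"D=50 Gy in 5 x 10 Gy at PTV edge, T=5 d; isocenter 5 x 12.5 Gy"
Inoue 2013,109,4,48,12,9.603082,105.6,75.3,81,25,FALSE,"D=45/48 Gy in 15/12 Gy fractions, T=4-7 d; BED matches 4 x 12 Gy"
Takeda 2013,109,5,62.493,12.498571,10,140.6,100,84.4,24,FALSE,"D=40/50 Gy in 8/10 Gy fractions at PTV edge, T=5 d"
Hamaji 2015,104,4,48,12,9.603082,105.6,75.3,76.7,43,FALSE,"D=48 Gy in 4 x 12 Gy, T=5 d"
Rwigema 2015,46,3,70.206,23.401878,18,234.5,151.2,95.5,16.8,FALSE,D=54 Gy in 3 x 18 Gy at PTV edge; Monte Carlo dose calculation
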