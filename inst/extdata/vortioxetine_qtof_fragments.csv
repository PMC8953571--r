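compound,condition,ion_type,mz_observed,ion_formula,mz_calculated,ppm_printed
VOR,none,molecular,299.1961,C18H23N2S,299.1981,-6.68
VOR,none,fragment,109.0364,C6H5S,109.0368,-3.67
VOR,none,fragment,120.1021,C8H10N,120.1011,8.32
VOR,none,fragment,150.0665,C8H8NS,150.0659,3.99
VOR,none,fragment,256.1512,C16H18NS,256.1508,1.56
DP1,photolytic,molecular,179.1172,C10H15N2O,179.1181,-5.02
DP1,photolytic,fragment,44.0503,C2H6N,44.05017,2.95
DP1,photolytic,fragment,70.0659,C4H8N,70.0663,-5.71
DP1,photolytic,fragment,85.0747,C4H9N2,85.0742,5.88
DP1,photolytic,fragment,92.0488,C6H6N,92.0493,-5.43
DP1,photolytic,fragment,106.0645,C7H8N,106.0651,-5.66
DP1,photolytic,fragment,108.0441,C7H6NO,108.0448,-6.48
DP1,photolytic,fragment,118.0660,C8H8N,118.0658,1.69
DP1,photolytic,fragment,136.0763,C8H10NO,136.0759,2.94
DP2,photolytic,molecular,163.1530,C10H15N2,163.1541,-6.74
DP2,photolytic,fragment,44.0659,C2H6N,44.0658,2.26
DP2,photolytic,fragment,77.0616,C6H5,77.0608,10.38
DP2,photolytic,fragment,106.0909,C7H8N,106.0914,-4.71
DP2,photolytic,fragment,118.0851,C8H8N,118.0856,-4.23
DP2,photolytic,fragment,120.1052,C8H10N,120.1054,-1.66
DP2,photolytic,fragment,146.0786,C10H12N,146.0791,-3.42
DP3,oxidative/photolytic,molecular,315.1308,C18H23N2OS,315.1317,-2.86
DP3,oxidative/photolytic,fragment,44.0673,C2H6N,44.0668,11.35
DP3,oxidative/photolytic,fragment,56.0697,C3H6N,56.0694,5.35
DP3,oxidative/photolytic,fragment,72.0678,C4H10N,72.0683,-6.94
DP3,oxidative/photolytic,fragment,94.0910,C6H8N,94.0915,-5.31
DP3,oxidative/photolytic,fragment,106.0929,C7H8N,106.0923,5.65
DP3,oxidative/photolytic,fragment,120.1103,C8H10N,120.1107,-3.33
DP3,oxidative/photolytic,fragment,136.0531,C7H6NS,136.0535,-2.94
DP3,oxidative/photolytic,fragment,138.0118,C7H8NS,138.0121,-2.17
DP3,oxidative/photolytic,fragment,148.0555,C8H6NS,148.0554,0.67
DP3,oxidative/photolytic,fragment,162.0729,C9H8NS,162.0731,-1.23
DP3,oxidative/photolytic,fragment,191.0128,C10H11N2S,191.0134,-3.14
DP3,oxidative/photolytic,fragment,209.1160,C10H13N2OS,209.1164,-1.91
DP3,oxidative/photolytic,fragment,242.1397,C15H16NS,242.1391,2.48
DP3,oxidative/photolytic,fragment,256.1594,C16H18NS,256.1598,-1.56
DP4,photolytic,molecular,347.1119,C18H23N2O3S,347.1121,-0.58
DP4,photolytic,fragment,44.0660,C2H6N,44.0663,-6.81
DP4,photolytic,fragment,56.0682,C3H6N,56.0679,5.35
DP4,photolytic,fragment,70.0860,C4H8N,70.0867,-9.99
DP4,photolytic,fragment,85.0375,C4H9N2,85.0371,4.70
DP4,photolytic,fragment,105.0971,C7H7N,105.0978,-6.66
DP4,photolytic,fragment,136.0504,C7H6NS,136.0507,-2.20
DP4,photolytic,fragment,304.0676,C16H18NO3S,304.0681,-1.64
DP5,oxidative,molecular,331.1060,C18H23N2O2S,331.1064,-1.21
DP5,oxidative,fragment,44.0652,C2H6N,44.0647,11.35
DP5,oxidative,fragment,77.7323,C4H15N,77.7326,-3.86
DP5,oxidative,fragment,91.0793,C7H7,91.0798,-5.49
DP5,oxidative,fragment,106.0926,C7H8N,106.0931,-4.71
DP5,oxidative,fragment,119.1755,C8H9N,119.1758,-2.52
DP5,oxidative,fragment,136.0527,C7H6NS,136.0533,-4.41
DP5,oxidative,fragment,140.0436,C6H6NOS,140.0441,-3.57
DP5,oxidative,fragment,162.3383,C9H8NS,162.3389,-3.70
DP5,oxidative,fragment,178.0349,C9H8NOS,178.0344,2.81
DP5,oxidative,fragment,190.0881,C10H10N2S,190.0876,2.63
DP5,oxidative,fragment,288.1306,C16H18N2O2S,288.1311,-1.73
DP6,photolytic,molecular,347.1125,C18H23N2O3S,347.1121,1.15
DP6,photolytic,fragment,56.0674,C3H6N,56.0678,-7.13
DP6,photolytic,fragment,70.1192,C4H8N,70.1197,-7.13
DP6,photolytic,fragment,84.3469,C4H8N2,84.3473,-4.74
DP6,photolytic,fragment,106.0865,C7H8N,106.0868,-2.83
DP6,photolytic,fragment,120.3363,C8H10N,120.3357,4.99
DP6,photolytic,fragment,134.0822,C7H4NS,134.0828,-4.47
DP6,photolytic,fragment,149.1328,C8H5NS,149.1317,7.38
DP6,photolytic,fragment,164.1592,C8H6NOS,164.1597,-3.05
DP6,photolytic,fragment,205.0757,C10H9N2OS,205.0763,-2.93
DP6,photolytic,fragment,223.0854,C10H11N2O2S,223.0862,-3.59
DP6,photolytic,fragment,304.1010,C16H18NO3S,304.1015,-1.64
DP7,oxidative,molecular,315.1527,C18H23N2OS,315.1517,3.17
DP7,oxidative,fragment,74.0845,C4H12N,74.0841,5.40
DP7,oxidative,fragment,106.1101,C7H8N,106.1108,-6.60
DP7,oxidative,fragment,120.1047,C8H10N,120.1053,-5.00
DP7,oxidative,fragment,136.0417,C7H6NS,136.0422,-3.67
DP7,oxidative,fragment,191.0902,C10H11N2S,191.0907,-2.62
DP7,oxidative,fragment,256.2938,C16H18NS,256.2942,-1.56
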