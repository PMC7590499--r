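prefix,group,category
A,any,infections
B,any,infections
G00,any,infections
J1,any,infections
C,any,malignant_neoplasms
D0,any,malignant_neoplasms
Q,any,congenital_malformations
P05,stillbirth,fetal_growth_restriction
P20,stillbirth,intrauterine_hypoxia
P21,stillbirth,intrapartum_hypoxia
P07,neonate,preterm_complications
P10,neonate,intrapartum_complications
P15,neonate,intrapartum_complications
P36,neonate,infections
O00,maternal,abortion
O03,maternal,abortion
O04,maternal,abortion
O05,maternal,abortion
O06,maternal,abortion
O07,maternal,abortion
O08,maternal,abortion
O14,maternal,eclampsia
O15,maternal,eclampsia
O20,maternal,obstetric_hemorrhage
O44,maternal,obstetric_hemorrhage
O45,maternal,obstetric_hemorrhage
O46,maternal,obstetric_hemorrhage
O67,maternal,obstetric_hemorrhage
O72,maternal,obstetric_hemorrhage
O85,maternal,infections
O86,maternal,infections
O,maternal,other_obstetric_complications
R99,any,non_conclusive
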