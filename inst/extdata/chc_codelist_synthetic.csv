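code,description,group
C91,Lymphoid leukaemia,cancer/blood
D56,Thalassaemia,cancer/blood
D610,Constitutional aplastic anaemia,cancer/blood
Q21,Congenital malformations of cardiac septa,cardiovascular
I42,Cardiomyopathy,cardiovascular
Q250,Patent ductus arteriosus,cardiovascular
J45,Asthma,respiratory
J448,Other specified chronic obstructive pulmonary disease,respiratory
P27,Chronic respiratory disease originating in the perinatal period,respiratory
G40,Epilepsy,neurological
G80,Cerebral palsy,neurological
Q05,Spina bifida,neurological
F84,Pervasive developmental disorders,mental health/behavioural
F90,Hyperkinetic disorders,mental health/behavioural
F50,Eating disorders,mental health/behavioural
K529,Noninfective gastroenteritis and colitis unspecified,metabolic and other
E10,Type 1 diabetes mellitus,metabolic and other
N18,Chronic kidney disease,metabolic and other
Q62,Congenital obstructive defects of renal pelvis,metabolic and other
M08,Juvenile arthritis,musculoskeletal/skin
Q66,Congenital deformities of feet,musculoskeletal/skin
L930,Discoid lupus erythematosus,musculoskeletal/skin
B20,Human immunodeficiency virus disease,chronic infections
B181,Chronic viral hepatitis B,chronic infections
R62,Lack of expected normal physiological development,non-specific
Z518,Other specified medical care,non-specific
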