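reaction_id,condition,mean,sigma,class,enzyme,metabolism
PTS_glc,control,-3.04,0.01824,FMT,Phosphotransferase system for D-glucose transport,Transport
PTS_glc,perturbed,-2.48,0.1488,FMT,Phosphotransferase system for D-glucose transport,Transport
GROWTH,control,0.20,0.0100,FMT,Cell growth rate,-
GROWTH,perturbed,0.22,0.0110,FMT,Cell growth rate,-
PGI,control,2.39,0.3107,C13,Glucose-6-phosphate isomerase,Glycolysis/Gluconeogenesis
PGI,perturbed,1.79,0.2327,C13,Glucose-6-phosphate isomerase,Glycolysis/Gluconeogenesis
PYK,control,1.09,0.0109,C13,Pyruvate kinase,Glycolysis/Gluconeogenesis
PYK,perturbed,0.26,0.0026,C13,Pyruvate kinase,Glycolysis/Gluconeogenesis
G6PDH,control,0.61,0.0732,C13,Glucose 6-phosphate dehydrogenase,Pentose phosphate pathway
G6PDH,perturbed,0.64,0.0768,C13,Glucose 6-phosphate dehydrogenase,Pentose phosphate pathway
GND,control,0.61,0.0732,C13,Phosphogluconate dehydrogenase,Pentose phosphate pathway
GND,perturbed,0.32,0.0384,C13,Phosphogluconate dehydrogenase,Pentose phosphate pathway
PPC,control,0.67,0.0469,C13,Phosphoenolpyruvate carboxylase,Anaplerotic reactions
PPC,perturbed,1.61,0.1127,C13,Phosphoenolpyruvate carboxylase,Anaplerotic reactions
PCK,control,0.07,0.0070,C13,Phosphoenolpyruvate carboxykinase,Anaplerotic reactions
PCK,perturbed,0.93,0.0930,C13,Phosphoenolpyruvate carboxykinase,Anaplerotic reactions
PDH,control,3.56,0.2136,C13,Pyruvate dehydrogenase,Glycolysis/Gluconeogenesis
PDH,perturbed,0.00,0.0000,C13,Pyruvate dehydrogenase,Glycolysis/Gluconeogenesis
AKGDH,perturbed,0.00,0.0000,C13,alpha-ketoglutarate dehydrogenase,Citrate Cycle (TCA)
GLYCL,perturbed,0.00,0.0000,C13,glycine cleavage system,Folate Metabolism
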