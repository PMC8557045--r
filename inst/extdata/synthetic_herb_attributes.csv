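herb,property,tastes,meridians
Gan-cao,Mild,Sweet,Heart;Lung;Spleen;Stomach
Huang-qi,Warm,Sweet,Lung;Spleen
Dang-gui,Warm,Sweet;Pungent,Liver;Heart;Spleen
Chuan-xiong,Warm,Pungent,Liver;Gallbladder;Pericardium
Yan-hu-suo,Warm,Pungent;Bitter,Liver;Spleen
San-qi,Warm,Sweet;Bitter,Liver;Stomach
Mai-dong,Cool,Sweet;Bitter,Heart;Lung;Stomach
Wu-wei-zi,Warm,Sour;Sweet,Lung;Heart;Kidney
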