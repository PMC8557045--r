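raw,canonical
Gancao,Gan-cao
Radix Glycyrrhizae,Gan-cao
Huangqi,Huang-qi
Danggui,Dang-gui
Chuanxiong,Chuan-xiong
Yanhusuo,Yan-hu-suo
Sanqi,San-qi
Maidong,Mai-dong
Wuweizi,Wu-wei-zi
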