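case_id,patient_id,herbs,syndromes
c001,p01,Gan-cao;Huang-qi;Dang-gui,qi deficiency;blood stasis
c002,p01,Gan-cao;San-qi,qi deficiency
c003,p02,Huang-qi;Dang-gui;Chuan-xiong,blood stasis;qi deficiency
c004,,Gan-cao;Yan-hu-suo,
c005,,Gan-cao;Yan-hu-suo,
c006,p03,San-qi;Yan-hu-suo;Gan-cao,qi deficiency;blood stasis
c007,,Huang-qi;Mai-dong;Wu-wei-zi,qi deficiency
c008,p04,Dang-gui;Gan-cao;Huang-qi,blood stasis;qi deficiency
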