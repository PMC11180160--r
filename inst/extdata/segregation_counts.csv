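assay,family_id,generation,class_labels,observed,ratio
phenotypic,M2xBs_F2,F2,seeded;seedless,48;10,3;1
phenotypic,M2xBs_BCBs,BC_Bs,seeded;seedless,8;6,1;1
dominant,M1xBs_F2,F2,presence;absence,99;43,3;1
dominant,M2xBs_F2,F2,presence;absence,190;71,3;1
dominant,M3xBs_F2,F2,presence;absence,69;33,3;1
dominant,M1xBs_BCBs,BC_Bs,presence;absence,48;61,1;1
dominant,M2xBs_BCBs,BC_Bs,presence;absence,57;59,1;1
dominant,M3xBs_BCBs,BC_Bs,presence;absence,26;30,1;1
codominant,M2xBs_F2,F2,INO_INO;INO_ino;ino_ino,34;70;41,1;2;1
codominant,M2xBs_BCM,BC_M,INO_INO;INO_ino,30;26,1;1
codominant,M2xBs_BCBs,BC_Bs,INO_ino;ino_ino,30;31,1;1
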