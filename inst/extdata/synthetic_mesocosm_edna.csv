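site_id,replicate,value,unit
site01,1,2123,copies_per_ml
site01,2,6376,copies_per_ml
site01,3,47,copies_per_ml
site02,1,4190,copies_per_ml
site02,2,2947,copies_per_ml
site02,3,3093,copies_per_ml
site03,1,254,copies_per_ml
site03,2,1826,copies_per_ml
site03,3,533,copies_per_ml
site04,1,3749,copies_per_ml
site04,2,1203,copies_per_ml
site04,3,1744,copies_per_ml
site05,1,652,copies_per_ml
site05,2,6452,copies_per_ml
site05,3,210,copies_per_ml
site06,1,1367,copies_per_ml
site06,2,145,copies_per_ml
site06,3,1210,copies_per_ml
site07,1,1933,copies_per_ml
site07,2,1515,copies_per_ml
site07,3,1812,copies_per_ml
site08,1,47,copies_per_ml
site08,2,855,copies_per_ml
site08,3,2,copies_per_ml
site09,1,1826,copies_per_ml
site09,2,1359,copies_per_ml
site09,3,1404,copies_per_ml
site10,1,131,copies_per_ml
site10,2,112,copies_per_ml
site10,3,48,copies_per_ml
site11,1,2195,copies_per_ml
site11,2,1247,copies_per_ml
site11,3,189,copies_per_ml
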