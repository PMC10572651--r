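table_id,true_class,normal,benign,malignant,printed_total
T1_train,normal,20,6,12,38
T1_train,benign,2,18,6,26
T1_train,malignant,6,4,22,32
T1_train,printed_column_total,28,28,40,96
T1_test,normal,12,2,0,14
T1_test,benign,18,11,4,33
T1_test,malignant,0,12,6,18
T1_test,printed_column_total,30,25,10,65
T2_train,normal,20,4,14,38
T2_train,benign,6,13,7,26
T2_train,malignant,9,7,26,42
T2_train,printed_column_total,35,24,47,106
T2_test,normal,16,3,0,19
T2_test,benign,12,18,4,34
T2_test,malignant,6,13,18,37
T2_test,printed_column_total,19,34,22,90
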