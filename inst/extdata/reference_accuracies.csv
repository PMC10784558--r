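model,train_accuracy_pct,test_accuracy_pct
SVM,82.13,74.00
GNB,85.63,78.00
LDA,78.50,69.00
DT,90.38,72.00
BiLSTM,87.30,87.00
WalshBiLSTM,99.60,94.00
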