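regime,method,train_accuracy_pct,test_accuracy_pct
I,Pure CNN,100.00,60.40
II,CNN + classic data augmentation,90.08,80.57
III,CNN + classic data augmentation + WGAN-GP,98.23,82.41
IV,CNN + classic data augmentation + WGAN-GP-LSR,97.84,84.78
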