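{"RA":["1","2","3","4","5","6","7","9","10","11","12","13","14","15"],"RB":["1","2","3","4","5","6","7","8","9","10","11","12","13","14","15"],"RC":["1","2","3","4","5","6","7","9","10","11","13","14","15"],"RD":["1","2","3","4","5","6","7","8","9","10","11","13","14","15"],"RE":["2","3","4","5","6","7","9","10","11","12","13","14","15"],"RF":["1","2","3","4","6","7","9","10","11","12","13","14","15"]}
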