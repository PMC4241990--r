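((((((((O_sativa_japonica:0.187,O_rufipogon:0.187):0.204,(O_sativa_indica:0.202,O_nivara:0.202):0.189):0.181,(O_glaberrima:0.120,O_barthii:0.120):0.452):0.166,O_glumaepatula:0.738):1.094,O_longistaminata:1.832):0.485,O_meridionalis:2.317):4.395,O_punctata:6.712):8.288,O_brachyantha:15);
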