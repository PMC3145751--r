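(((t02:0.05171479532,t04:0.05171479532):0.3388818454,((t08:0.1759880192,t01:0.1759880192):0.02911730612,t07:0.2051053253):0.1854913154):0.2094033593,(t05:0.2613753364,(t03:0.2330268287,t06:0.2330268287):0.02834850771):0.3386246636,OUT:0.6);
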