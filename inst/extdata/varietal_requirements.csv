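crop,accumulated_cold_base,group_label,group_range,heat_start
peach,250,Very Low,<250,125
peach,500,Low,250-500,250
peach,750,Medium,500-750,375
peach,1000,Medium-High,750-1000,500
peach,1250,High,1000-1250,625
apricot,600,Low,500-700,300
apricot,800,Medium,700-900,400
apricot,1000,Medium-High,900-1100,500
apricot,1250,High,>1100,600
japanese_plum,625,Low,500-700,315
japanese_plum,800,Medium,700-900,400
japanese_plum,1000,High,>1000,500
sweet_cherry,625,Low,500-750,315
sweet_cherry,825,Medium,750-1000,415
sweet_cherry,1000,High,>1000,500
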