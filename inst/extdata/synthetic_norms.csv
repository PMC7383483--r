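"jaw","position","sex","mean_mm","sd_mm"
"maxilla",1,"M",8.5,0.45
"mandible",1,"M",8.5,0.45
"maxilla",1,"F",8.5,0.45
"mandible",1,"F",8.5,0.45
"maxilla",2,"M",6.5,0.45
"mandible",2,"M",6.5,0.45
"maxilla",2,"F",6.5,0.45
"mandible",2,"F",6.5,0.45
"maxilla",3,"M",7.5,0.45
"mandible",3,"M",7.5,0.45
"maxilla",3,"F",7.5,0.45
"mandible",3,"F",7.5,0.45
"maxilla",4,"M",7,0.45
"mandible",4,"M",7,0.45
"maxilla",4,"F",7,0.45
"mandible",4,"F",7,0.45
"maxilla",5,"M",6.8,0.45
"mandible",5,"M",6.8,0.45
"maxilla",5,"F",6.8,0.45
"mandible",5,"F",6.8,0.45
"maxilla",6,"M",9.5,0.45
"mandible",6,"M",9.5,0.45
"maxilla",6,"F",9.5,0.45
"mandible",6,"F",9.5,0.45
"maxilla",7,"M",9,0.45
"mandible",7,"M",9,0.45
"maxilla",7,"F",9,0.45
"mandible",7,"F",9,0.45
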