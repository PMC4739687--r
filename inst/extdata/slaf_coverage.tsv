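sample	read_length_bp	read_number	gc_percent
Shouxing	80	845612	86.67
Xinguowei	80	1703803	83.65
Sweet	80	3113710	85.33
Sour	80	3671547	82.70
Non-sweet_non-sour	80	3103598	84.47
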