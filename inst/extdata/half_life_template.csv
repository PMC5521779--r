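"xxx","yyy","half_life_days"
"G","G",NA
"S","G",NA
"T","G",NA
"C","G",NA
"M","G",NA
"F","G",NA
"Y","G",NA
"D","G",NA
"E","G",NA
"H","G",NA
"K","G",NA
"R","G",NA
"A","G",NA
"L","G",NA
"V","G",NA
"I","G",NA
"W","G",NA
"P","G",NA
"G","H",NA
"S","H",NA
"T","H",NA
"C","H",NA
"M","H",NA
"F","H",NA
"Y","H",NA
"D","H",NA
"E","H",NA
"H","H",NA
"K","H",NA
"R","H",NA
"A","H",NA
"L","H",NA
"V","H",NA
"I","H",NA
"W","H",NA
"P","H",NA
"G","S",NA
"S","S",NA
"T","S",NA
"C","S",NA
"M","S",NA
"F","S",NA
"Y","S",NA
"D","S",NA
"E","S",NA
"H","S",NA
"K","S",NA
"R","S",NA
"A","S",NA
"L","S",NA
"V","S",NA
"I","S",NA
"W","S",NA
"P","S",NA
"G","A",NA
"S","A",NA
"T","A",NA
"C","A",NA
"M","A",NA
"F","A",NA
"Y","A",NA
"D","A",NA
"E","A",NA
"H","A",NA
"K","A",NA
"R","A",NA
"A","A",NA
"L","A",NA
"V","A",NA
"I","A",NA
"W","A",NA
"P","A",NA
"G","D",NA
"S","D",NA
"T","D",NA
"C","D",NA
"M","D",NA
"F","D",NA
"Y","D",NA
"D","D",NA
"E","D",NA
"H","D",NA
"K","D",NA
"R","D",NA
"A","D",NA
"L","D",NA
"V","D",NA
"I","D",NA
"W","D",NA
"P","D",NA
"G","T",NA
"S","T",NA
"T","T",NA
"C","T",NA
"M","T",NA
"F","T",NA
"Y","T",NA
"D","T",NA
"E","T",NA
"H","T",NA
"K","T",NA
"R","T",NA
"A","T",NA
"L","T",NA
"V","T",NA
"I","T",NA
"W","T",NA
"P","T",NA
"G","C",NA
"S","C",NA
"T","C",NA
"C","C",NA
"M","C",NA
"F","C",NA
"Y","C",NA
"D","C",NA
"E","C",NA
"H","C",NA
"K","C",NA
"R","C",NA
"A","C",NA
"L","C",NA
"V","C",NA
"I","C",NA
"W","C",NA
"P","C",NA
"G","K",NA
"S","K",NA
"T","K",NA
"C","K",NA
"M","K",NA
"F","K",NA
"Y","K",NA
"D","K",NA
"E","K",NA
"H","K",NA
"K","K",NA
"R","K",NA
"A","K",NA
"L","K",NA
"V","K",NA
"I","K",NA
"W","K",NA
"P","K",NA
"G","M",NA
"S","M",NA
"T","M",NA
"C","M",NA
"M","M",NA
"F","M",NA
"Y","M",NA
"D","M",NA
"E","M",NA
"H","M",NA
"K","M",NA
"R","M",NA
"A","M",NA
"L","M",NA
"V","M",NA
"I","M",NA
"W","M",NA
"P","M",NA
"G","E",NA
"S","E",NA
"T","E",NA
"C","E",NA
"M","E",NA
"F","E",NA
"Y","E",NA
"D","E",NA
"E","E",NA
"H","E",NA
"K","E",NA
"R","E",NA
"A","E",NA
"L","E",NA
"V","E",NA
"I","E",NA
"W","E",NA
"P","E",NA
"G","R",NA
"S","R",NA
"T","R",NA
"C","R",NA
"M","R",NA
"F","R",NA
"Y","R",NA
"D","R",NA
"E","R",NA
"H","R",NA
"K","R",NA
"R","R",NA
"A","R",NA
"L","R",NA
"V","R",NA
"I","R",NA
"W","R",NA
"P","R",NA
"G","F",NA
"S","F",NA
"T","F",NA
"C","F",NA
"M","F",NA
"F","F",NA
"Y","F",NA
"D","F",NA
"E","F",NA
"H","F",NA
"K","F",NA
"R","F",NA
"A","F",NA
"L","F",NA
"V","F",NA
"I","F",NA
"W","F",NA
"P","F",NA
"G","Y",NA
"S","Y",NA
"T","Y",NA
"C","Y",NA
"M","Y",NA
"F","Y",NA
"Y","Y",NA
"D","Y",NA
"E","Y",NA
"H","Y",NA
"K","Y",NA
"R","Y",NA
"A","Y",NA
"L","Y",NA
"V","Y",NA
"I","Y",NA
"W","Y",NA
"P","Y",NA
"G","W",NA
"S","W",NA
"T","W",NA
"C","W",NA
"M","W",NA
"F","W",NA
"Y","W",NA
"D","W",NA
"E","W",NA
"H","W",NA
"K","W",NA
"R","W",NA
"A","W",NA
"L","W",NA
"V","W",NA
"I","W",NA
"W","W",NA
"P","W",NA
"G","L",NA
"S","L",NA
"T","L",NA
"C","L",NA
"M","L",NA
"F","L",NA
"Y","L",NA
"D","L",NA
"E","L",NA
"H","L",NA
"K","L",NA
"R","L",NA
"A","L",NA
"L","L",NA
"V","L",NA
"I","L",NA
"W","L",NA
"P","L",NA
"G","V",NA
"S","V",NA
"T","V",NA
"C","V",NA
"M","V",NA
"F","V",NA
"Y","V",NA
"D","V",NA
"E","V",NA
"H","V",NA
"K","V",NA
"R","V",NA
"A","V",NA
"L","V",NA
"V","V",NA
"I","V",NA
"W","V",NA
"P","V",NA
"G","I",NA
"S","I",NA
"T","I",NA
"C","I",NA
"M","I",NA
"F","I",NA
"Y","I",NA
"D","I",NA
"E","I",NA
"H","I",NA
"K","I",NA
"R","I",NA
"A","I",NA
"L","I",NA
"V","I",NA
"I","I",NA
"W","I",NA
"P","I",NA
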