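["AAC1","AAC2","AAC3","AAC4","AAC5","AAC6","AAC7","AAC8","AAC9","AAC10","AAC11","AAC12","AAC13","AAC14","AAC15","AAC16","AAC17","AAC18","AAC19","AAC20","APAAC1","APAAC2","APAAC3","APAAC4","APAAC5","APAAC6","APAAC7","APAAC8","APAAC9","APAAC10","APAAC11","APAAC12","APAAC13","APAAC14","APAAC15","APAAC16","APAAC17","APAAC18","APAAC19","APAAC20","APAAC21","APAAC22","APAAC23","APAAC24","APAAC25","APAAC26","APAAC27","APAAC28","APAAC29","APAAC30","Blosum1","Blosum2","Blosum3","Blosum4","Blosum5","Blosum6","Blosum7","Blosum8","CTDC1","CTDC2","CTDC3","CTDC4","CTDC5","CTDC6","CTDC7","CTDC8","CTDC9","CTDC10","CTDC11","CTDC12","CTDC13","CTDC14","CTDC15","CTDC16","CTDC17","CTDC18","CTDC19","CTDC20","CTDC21","CTDD1","CTDD2","CTDD3","CTDD4","CTDD5","CTDD6","CTDD7","CTDD8","CTDD9","CTDD10","CTDD11","CTDD12","CTDD13","CTDD14","CTDD15","CTDD16","CTDD17","CTDD18","CTDD19","CTDD20","CTDD21","CTDD22","CTDD23","CTDD24","CTDD25","CTDD26","CTDD27","CTDD28","CTDD29","CTDD30","CTDD31","CTDD32","CTDD33","CTDD34","CTDD35","CTDD36","CTDD37","CTDD38","CTDD39","CTDD40","CTDD41","CTDD42","CTDD43","CTDD44","CTDD45","CTDD46","CTDD47","CTDD48","CTDD49","CTDD50","CTDD51","CTDD52","CTDD53","CTDD54","CTDD55","CTDD56","CTDD57","CTDD58","CTDD59","CTDD60","CTDD61","CTDD62","CTDD63","CTDD64","CTDD65","CTDD66","CTDD67","CTDD68","CTDD69","CTDD70","CTDD71","CTDD72","CTDD73","CTDD74","CTDD75","CTDD76","CTDD77","CTDD78","CTDD79","CTDD80","CTDD81","CTDD82","CTDD83","CTDD84","CTDD85","CTDD86","CTDD87","CTDD88","CTDD89","CTDD90","CTDD91","CTDD92","CTDD93","CTDD94","CTDD95","CTDD96","CTDD97","CTDD98","CTDD99","CTDD100","CTDD101","CTDD102","CTDD103","CTDD104","CTDD105","CTDT1","CTDT2","CTDT3","CTDT4","CTDT5","CTDT6","CTDT7","CTDT8","CTDT9","CTDT10","CTDT11","CTDT12","CTDT13","CTDT14","CTDT15","CTDT16","CTDT17","CTDT18","CTDT19","CTDT20","CTDT21","Geary1","Geary2","Geary3","Geary4","Geary5","Geary6","Geary7","Geary8","Geary9","Geary10","Geary11","Geary12","Geary13","Geary14","Geary15","Geary16","Geary17","Geary18","Geary19","Geary20","Geary21","Geary22","Geary23","Geary24","Geary25","Geary26","Geary27","Geary28","Geary29","Geary30","Geary31","Geary32","Geary33","Geary34","Geary35","Geary36","Geary37","Geary38","Geary39","Geary40","PAAC1","PAAC2","PAAC3","PAAC4","PAAC5","PAAC6","PAAC7","PAAC8","PAAC9","PAAC10","PAAC11","PAAC12","PAAC13","PAAC14","PAAC15","PAAC16","PAAC17","PAAC18","PAAC19","PAAC20","PAAC21","PAAC22","PAAC23","PAAC24","PAAC25","PAAC26","PAAC27","PAAC28","PAAC29","PAAC30","PsePC1","PsePC2","PsePC3","PsePC4","PsePC5","PsePC6","PsePC7","PsePC8","PsePC9","PsePC10","PsePC11","PsePC12","PsePC13","PsePC14","PsePC15","PsePC16","PsePC17","PsePC18","PsePC19","PsePC20","PsePC21","PsePC22","PseSC1","PseSC2","PseSC3","PseSC4","PseSC5","PseSC6","PseSC7","PseSC8","PseSC9","PseSC10","PseSC11","PseSC12","PseSC13","PseSC14","PseSC15","PseSC16","PseSC17","PseSC18","PseSC19","PseSC20","PseSC21","PseSC22","PseSC23","PseSC24","PseSC25","PseSC26","Charge","Boman","aIndex","autocov","Crosscov1","Crosscov2","Crucian1","Crucian2","Crucian3","fasgai1","fasgai2","fasgai3","fasgai4","fasgai5","fasgai6","Hmoment1","Hmoment2","hydrophobicity","Instaindex","mswhim1","mswhim2","mswhim3","pI","protFP1","protFP2","protFP3","protFP4","protFP5","protFP6","protFP7","protFP8","stscales1","stscales2","stscales3","stscales4","stscales5","stscales6","stscales7","stscales8","tscales1","tscales2","tscales3","tscales4","tscales5","vhsescales1","vhsescales2","vhsescales3","vhsescales4","vhsescales5","vhsescales6","vhsescales7","vhsescales8","zscales1","zscales2","zscales3","zscales4","zscales5","QSO1","QSO2","QSO3","QSO4","QSO5","QSO6","QSO7","QSO8","QSO9","QSO10","QSO11","QSO12","QSO13","QSO14","QSO15","QSO16","QSO17","QSO18","QSO19","QSO20","QSO21","QSO22","QSO23","QSO24","QSO25","QSO26","QSO27","QSO28","QSO29","QSO30","QSO31","QSO32","QSO33","QSO34","QSO35","QSO36","QSO37","QSO38","QSO39","QSO40","QSO41","QSO42","QSO43","QSO44","QSO45","QSO46","QSO47","QSO48","QSO49","QSO50","QSO51","QSO52","QSO53","QSO54","QSO55","QSO56","QSO57","QSO58","QSO59","QSO60","SOCN1","SOCN2","SOCN3","SOCN4","SOCN5","SOCN6","SOCN7","SOCN8","SOCN9","SOCN10","SOCN11","SOCN12","SOCN13","SOCN14","SOCN15","SOCN16","SOCN17","SOCN18","SOCN19","SOCN20","cTP","mTP","SP","TM","other","NLS","erpred","SVM_mito","SVM_mem","SVM_inter","SVM_matrix","SVM_outer","Tango1","Tango2","Tango3","Tango4","Tango5","Tango6","Homology"]
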