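eye,location,iop_mmhg,ad_true,ad_mm
Eye1,S,10,0.3425894574635695,0.18700913877466405
Eye1,S,15,0.3279190655728179,0.27432098192503357
Eye1,S,20,0.31480927470893505,0.19166288182928107
Eye1,S,25,0.30291776989075636,0.28771359052542667
Eye1,I,10,1.123892238921501,1.0336342125648912
Eye1,I,15,0.6731559908545783,0.5469684565090456
Eye1,I,20,0.5735486413750035,0.6708067556127751
Eye1,I,25,0.5159379600030967,0.535783451419787
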