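canonical,class,synonyms
olaparib,PARP_INHIBITOR,lynparza
niraparib tosylate monohydrate,PARP_INHIBITOR,niraparib;zejula;niraparib tosylate
rucaparib camsylate,PARP_INHIBITOR,rucaparib;rubraca
bevacizumab,MAB,avastin;mvasi;zirabev
mirvetuximab soravtansine-gynx,ADC,mirvetuximab soravtansine;mirvetuximab;elahere
carboplatin,CHEMOTHERAPY,paraplatin
cisplatin,CHEMOTHERAPY,platinol
cyclophosphamide,CHEMOTHERAPY,cytoxan;endoxan
gemcitabine hydrochloride,CHEMOTHERAPY,gemcitabine;gemzar
doxorubicin hydrochloride,CHEMOTHERAPY,doxorubicin;adriamycin
doxorubicin hydrochloride liposome,CHEMOTHERAPY,liposomal doxorubicin;doxorubicin hydrochloride liposomal;doxil;caelyx
topotecan hydrochloride,CHEMOTHERAPY,topotecan;hycamtin
paclitaxel,CHEMOTHERAPY,taxol
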