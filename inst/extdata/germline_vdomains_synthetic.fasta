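>TRAV38-2
VGAMTWVSIFGRWSELFGVTDKCTMNGKF......FNQLFWWEVWHHDEMHMKGRVIF.....QVLPLNETG.RTIWVRG..R..SKFFIMWQYTLPLNADHAC
>TRAV13-2
VGAMAWVSIFGIWSELFGSSHKCAHNSKF......FWQFWWWEVWHHDPIHMKGDVMF.....QMLPLTETG.RGYWVWG..R..HKFFIMWQYTPPLNTKHAC
>TRAV13-1
VGAMAWVSIFGIWSELFGSSHKCAHNSPF......FWQFWWWEVWHHDPIHMKGDVMF.....QMLPLTETG.RGYWVWG..R..HKFFIMWQYTPPLNLKHAC
>TRAV23
VGAMTWVSIFGRWSELFGVSDHCTMQSKF......FWQLFWWKVWHHDTMHMKGDVMF.....QMLPLNETG.RNDWVWY..R..SKFFIMWQYTPPLSTKHAC
>TRAV29
VGAMTWVSIFGRWSELFGVSDKCAGNSKK......FWFFFWWEHWYHDEIHQKGDVIF.....QMRPLNETG.PGDWVWG..R..SKFFIMWQYTLPLNTKHAC
>TRAV24
VGHMTWVSINWRWSELFGSTDWCTMNSKF......SWQFFWWEVWHHDEIHMKGDVIF.....QMNPLNETG.RDDWVWG..R..HKFFIMWQYTPPYNTKHAC
>TRAV12-3
VTAMAWVSIMGRWSELFGVSDGCAMNSKF......FWQLFWWNVWIHDEMHAKGRVIF.....QMLPLNETG.RGDWVWG..R..HPFFIMWQYTLSLNTKHAC
>TRAV25
VGAMTWVSIFGRWSELFGSTDKCANNSKF......FWQLFWWEVWHHDEMHLKGDVEF.....QMLPLNETG.FGDWVWD..R..SKYFIMWQYRPPLNTKHSC
>TRAV20
VGAMAWVSIIGRWSERFGSSDKCTMNSKF......FWALPWWEVWHHDEMHMKNRVIF.....QMLPLNETG.RRDWHWG..R..SKFFIMWQVTPPLNTKHAC
>TRBV7-8
RGRTNMMARYRRSHSNGIIVWDCHSSDNM......LADDNWDQMGMVVGERRAGEQNV.....FNVLVQVAV.NDKTEGQ..P..AYASHTMKLLEESSTAHNC
>TRBV5-1
RGLTNMMARYRRSHSNGIVVWDCHHSDPP......LADDAWDQMGMVVGELRANYQHV.....FNVLVPQAV.ADKTEGQ..P..AYASHTMILLEWSSTAHNC
>TRBV7-3
RRLTNMMASNRRVHSRGVVVWDCHHSDMP......LAIDNWDRMRMQVGERRAGEQVV.....FNVLVQVAV.ADKTEGQ..P..AYGSHTMILLEWSSTLHNC
>TRBV7-9
RRLTNMMASNRRVHSRGVVVWDCHHSDMP......LAIDNWDRMRMQVNERRAGEQVV.....FNVLVQVAV.ADKTEGQ..P..AYGSHTMILMEWSSTLHNC
>TRBV9
RGLTNMMASNRVSHSNLVVVWDCHHSRMP......LADDNWDRMVMVVGERRAGEQNV.....FNVLVQVAV.ADKTLGQ..P..AYGSHEMILLEWESTAHLC
>TRBV2
RGLTMMMASNRRSHKNGVVVYDCEHSDMP......LADDNWTRMGMVVGERRAGEQNV.....FNVLVQVAV.QDKTEGQ..P..AYGSVTMILLEWVSTAHNC
>TRBV6-5
SGLTNMGARNRRWHSNGIVVWDCHHSDMP......LADDNWDRGGGVVGERRAGEQNV.....FNVLVQVTV.ADKTEDQ..Y..AYASHTMILLEWSSTAHNC
>TRBV20-1
RGLTNMMERNRRSHSNGVVVWDCYHSDMP......LANDNWDRMGSRVGERRAGEQNV.....FNVLVQVAP.ADKTEGQ..P..AYGSHTMILLEWSAGAHNC
>TRBV18
RGLTNMMYSYRRSHSNGVVVWDCNHSDMP......LADDKWDQMGFVVGERRAGEQNV.....PNVLDQVAV.ADKTEGQ..P..WSASHTMILLEWSSTAHNC
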