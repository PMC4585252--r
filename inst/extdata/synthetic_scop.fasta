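>d010005 aldehyde ferredoxin oxidoreductase domain 1
LPSSDVPKFIRMTDQGELIHMPYNLEEPEVGAKYGQLQETRVEILYNALEIRTNIKIRQQDWQRLSTMGMDWQSLGIHINNCLHVEALPYRGGQEGRLALEFRVLLNWALDFFCFKVPHALKKNKTIAPVSEDTTQCIMSHSFATP
>d010006 aldehyde ferredoxin oxidoreductase domain 2
IPSLDVPKFILMCDQGELIHGPYNYPEPEYGAKYGQLMETRVEGLPNALMIRTNIKIDQQDWQRLSFMGMDQQSLGIHINNCLHVEALCYRGGQEGLLAWEFRVLLNWMLDFFCFKVPEALKSNKTIAPVSSDTTMTIMSHSFATP
>d010010 aconitase iron-sulfur domain domain 1
GRLSLLIDLTISALPKYIGSTEDVSNIVKANAITSNEAATPERTLMPSECPMRTTTLPTALNETEGFPFASDYDFAITDLYAQLWPGQWFDLIEQNKAVVVVTNLDCPKFNREVE
>d010011 aconitase iron-sulfur domain domain 2
GRLSLLIDLTISAGPKYIGGTEDVSNIVKGAAITSNNAATEERLLMPSVCPNRDTTLPTALNKTHGFPFRSDYDAAIANVYAQLDPGHGFDLFEQNKAVVFVTYLECPKIMDCVN
>d010012 aconitase iron-sulfur domain domain 3
GRLSLLIDLTISALPKYIGGTEDVSNIVKAAAITVNNCATPNRLLMPGECPNRDTTLPTALHKTEGRFFHADYDACITDLYAQLWPGQGFDLIEPNKAVVVVTYSECPKINREVE
>d010017 cytochrome c oxidase subunit I-like (heme-copper oxidase) domain 1
TTDGISSPPKEDFYRDTPDEKNRPGGSASITSSNLPTRFIMWVWQLNKCELGFTSPYVGGEKGHDVINLGIRRGLGDPAQDLHVPDSARGGCAGDIRATMKQEVHRLCDCSALAINHTKLQQTEEVATYQFWSRHAY
>d010018 cytochrome c oxidase subunit I-like (heme-copper oxidase) domain 2
TTDGKSSPPKLDFLEDTMDEKNRPGGSASITSSNPPTRFDMWVLQANKCELGFTSPYVGGEKGHDKFNAGIRRGVLDPAQYLHVPDGARGGCAGDIRATMKQEVHRLLDCSFLAINHTKLQQTEEVASYQFWSRHAP
>d010019 cytochrome c oxidase subunit I-like (heme-copper oxidase) domain 3
TTYYISSPPKEDFYDDTLDEKPKPGGSASITSSNPPTRTDMWVWQLNKCELGFTSPYWGGEKGHDKFNAGVRRGWGDPAQYLHCPRGARGGCANDIRATMKQEVHRGLDLSMLNINHNKLPQTEEEASYQFWSRHAP
>d010024 copper-containing nitrite reductase NirK
PIGGDLTDEPFAIRTEQLDVDSTRDKIVGLPAMLIGNIGHWINTEGLQLVWTVTIAIFAIVLMRGVDSPTLGRVTYSPDPENGTPGSLLQND
>d010025 multicopper oxidase CueO
MIGGDLTDEPFAIWTEGLDVPSTRDKIVGLPAFLIDPIGHSHNTEGLQLVWTVTIAIFVIVLGRGVDSPTLQEVTYSPDPENGQPGSLLQAD
>d010026 copper-containing nitrite reductase, NirK-type
MIGGDLTDEPFPIRFEALDVDWTRDQIVGLPASLIDNWGHSIFTEGPQLVWRVTIAIFAIVLGRGVDSPTLQRVTYFPDPENGQPGSLLQND
>d010027 blue multidomain copper protein of unknown function
MIGGDLTDEGFAIRTEQLDVDCTDDKIVGLPASLIDNIKHSYNTEGLQLVWTLTIAIFAIVLGRGVDDPTLQRVWYSEDPQNGQPGSLLQND
>d010029 plastocyanin/azurin-like domain 1
DRADDTVDDESFAHLAKCKDSGDVKPHLRLWSRKHEVSALLTYVHPDAGSPIRESLANGKRFGFGLADAIFNETVDEQIMALIFDNTDKQRFPAIGKFDMGRKYFKLAGFALANSPTIANPHVVDKSELECSQFSGLEIAQVQLTKTAGMLRVDPSVFGKKNMFPIPEGSSVARL
>d010030 plastocyanin/azurin-like domain 2
GCNDDTVDDESFAKLAQCKISGDGKPHLRLWSRVHEVSALLTYVHPDAGSPNRELLANGKRKGAPLAVSIFYETRNYQIMALLFDNSDKQRFAAIGKFDMGAKGDKLNGAKLANSPGISNPHVLDKSFLECSQFSGLEICQVQLTKTAGMLRVHPSVTGKKPMFPDPEGSSGARL
>d010031 plastocyanin/azurin-like domain 3
DQNDDTPDDESGAKLAQCKDSGDGKPHLRQWSRVHEVSALLTYVHPDAGSPGRELLANGKRKCAGLAVSIFNETYDEQPMADINDNTDKQRFAAIGKFDMGAVRQKLAGAALAWSPTISNPHVLDKSELECSSFSGLEIWQVQLTKTAGMLRVDPSVTGKKPIVPIPEGSKGAIL
>d010032 plastocyanin/azurin-like domain 4
DCNDDTVDDESFAKLAQCKDAGCGKHHLRLDSRVHEYSAWLTYNHPDAGSPGCESLANIKRKGAGLAVSVFQEMVDEQIMALMFDNTTCQRIAAIGKAFMGQKGFKLAGAALANLPTISNPHVEDKSELECSQFSGLYHWQVQFTKTAGMLRVDPSVTGKKPEFPIPEGSSGARL
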