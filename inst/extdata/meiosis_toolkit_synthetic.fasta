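>Spo11-2_ref
FHEVNYWLMVIYNYICKMVTKGIHTVHWVAYLAMCVEQNTIRHTSTWIWEAWAATGMKQM
DNNSWMNWIFWNQMIVSAHTMQVRDDTHYKMDQDSCYHKLPEALGEKIPNQLTQSLARDP
KLSFQMTMVYWHTQIGRYRTWGSVSRKPQLPWCHDGVQDHVESNAQEPGMMYCWIDCTHP
YNTCENNTWYHAIPMVTNIYQCSRQYMPAYCDSQSMQLCSDTSVMQGFDRVRKSSATEKL
DALGHRMIGN
>Mer3_ref
WLHPEQDVLYKYTWFSDWFGWVFACLAPCEEGDHMFMRAMQCAPTMKKITVYIVGDYFIW
GVCEWQTAGFPHPWHRSPPWTAGCLMWAATDKFRMFEVFWHKPIVRCLAAHNFIKNPDRD
GWTPLSAALHGNYPIMWERNLMILEQVYLPNFTTKVHNRPCFIPFPWRECSYIRIIYNMI
INCQMADNINNKNYYVSQFRCVFCDTTNCHRNGLTIEAHLWRFMMLDNFYFHNPDFAMHK
WPHDFCTTPL
>Hop1_ref
HKIQGRWWSLFQRGLRFHYYDRLSNVYPMCCKLAVYINGGPLRETPCHTIPPAKIMTQMF
QHGDQADNHCVWTRHSIRNDGLWHWQRWSHDTTPSHAMVGRSRWSDPQKPLPRGRYKVPQ
QYGVAPDVNNTHNKAPFWPWEQFHECRQDWLWDSIDNENSTWFTQVDHQQYCVTFNCDGV
LIGRDFGYTADTCCMWTYFWPCEQVTISKVPRNGWSVPIENPQHECDAALRICFSNWGFY
VLNLHWNPAF
>Dmc1_ref
DFKGFVVMCGNCQYYYQYGYGHAQMAFHEDTASDAWNAFGHYWMYHDTWGMCPVFLRCKP
GSEVWTWSYTPIKMVLHALPNNIVGGDYACPGHMSSRLCAPLQDFTDRMSVQYGYFNPPP
NFTEAAGLMRAKMMYCSYHVCFQHHKYTCDCHQCRQLYLGSGWQFNKAQPGSIAYQKWPA
IKGNGNFDYYLTKFILSPCKQCRENYMVVFTSAIMYRFPSDFDGYGKTYDMVCLGAVFKA
WWYYYEFCMR
>Hop2_ref
SDDDGCLRGRYIEMLPKMLLTRGRCNGWCTVSKYQIRLQCITVEVIRLRTDHAPQILDEW
VCRSHEAEDFECHCSWVFKWTSFVYPHQGAEDLNICKSQTDIMSCDQRWYQEKMPMLICA
AYCYVDTSPLWQCRPLVDEHCNWTHNCDRNQFLPMDWNMKRGTWHTPSPNSRLGQFMFPH
PTGGCLPFNWHCHNAWTKTGFQKKTQPQTHWQLSNDAMVPSLVVCNGWLKCPTPSHHQMM
NISVKNNQDR
>Mnd1_ref
EGYMSPPLPQDHRWTHVKVTFAEPPAVAMVDTHPYVVGMGVNAVDVFSRATHPCEEDECS
VDIIHMRIYPCECSNKIMRCLCARTITYNFSIRITVEPKNCMYHHFCVAHRHYWALEEEP
KLGDHSMWQSREEMCCFCGANNLTPKYQWPRIHGTWTIPPQQVVACWHHSRLHIRERGSE
RNVVCWEPERGEAHQPNIMKYPHMHMYFDVTYALWDWMNCDHSICIIETCHFYHVKLYHW
MNRMQNDEWH
>Msh4_ref
TPIFGCNSHPYHDTERTERSKDNENYWIPQGVWMNYPVIFCVKGPACTRSPSSLYRTCLC
QVAQTWCAVDMMQMMYKQCACMFRQFGKYRYCGSLVLWPINASWQLNVSQKTQSAWPDLH
QFMMQRPFNNQRRKFMMMQRWIGMKCSRGAASHQMCYNGMVSVTKTQANCNNNRVTFSWH
RNSNPFYGPEDFNVQFLLESDSPEIENTVDVEANHYMMTEVWGIHTPFNGQNDTWQEFRT
ADCCRMYYHV
>Msh5_ref
NYYTCIENEMNDEAEGRTNFDYWFAEKNKVWPYNYADWNNLDQCVKITRRFGHDYHGGMG
RCPGPAPIGMFRMQRKFMAGECGDQRSDRHECTWYRTVCPYSSKALQVYYNNQNNFSAMP
HLCHWVNSTCMWQVWYFHNNYTRLEPRCEMKLTAEYNWSLKSPPHKSPKMPLCDHCWTGD
TWMNFMDEHKKISIYHYDPCNDRLPRQHSNRLNDYFATQRLTYNEWWKNYRRTITRSSGR
PDTCPQMYED
>Rec8_ref
DHYSEIQEQMWPQWNRMRCQIVEQRQTHMSIKFLCSPRDCIGLKNIEFYSENMCCQYSMW
LEQAMGAKHVCKPKMYPHQWKNMGRWWEWRRFLLDSHDQDWVENKNRAWEAGLLRSEPWR
AGLCDYIEMQMERYYVSFRWNKGMITTHIMLFDKHLEWLCENTYCMMGPQTQRYPWWHPG
LQHRIWRDLWGRNHLVCNHLIRLLRYYVNLKLKYGMNGAWGRISMANMLDCCQQTPVSEW
FTGDKQTYWG
>Rec8_decoy
SHTSEQGCQMQIWCNFTGCCTKLSWQLAFSFKAYLGYHDWIWLKICEGQPCNRLCQYYTW
WHFVMAAAHWWVEKMAPTQIWMEGMGVITPRFKHDAFFYGVCELYHKMWTAPWERTPPWR
DASRESMEYWANIYVHSFLLDYRMLMNSEMMFPEILIWLCLNNYCMIRCQDARGEWWCPV
LKFRIEHEMVGRNHLVKNLAEENHRYYVAAKNGYDTNGAEGKIAVMMKQHCCDQTGRSEW
FRTHSNPDWG
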