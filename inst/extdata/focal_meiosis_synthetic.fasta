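>cand_Spo11-2
FHEQNYWLMVIYNYICKMETKGIHTVHTVYYLANCVEQNTIRHTSTWIWEAWAATGMHQM
DNNSWMNWIFWNQMIVSAHTMQVRDDTHYKMDPGSCYHKLPEALGEKIPNQLTQSKARDP
KKSFQMTMVGWHTQIGRYRTWGSVSRKPQLPDCHDGVQDHVESNAIEPGMMYCWIGWTHP
YNTCENNTWYHAYPMVTNIYQCSRQYMPDYCDSQSMQLCSDTSVMQGFDGVRKSSATEKL
DSLGHRMIGN
>cand_Mer3
WLHPNQDSLYKYTWFSDWFKWVFACLAPCEEGDHMFMRAMQCAPVMKKITVYIVGWHFIW
GVCTWQTEGFPHPWHRSPPWTIKCLMWAATDKFRMFEVFWHKPIVRCLAAHNFIKNFDRD
GWTPLSAALHGNYPIMWERNLMILEQVGLDNFTTYVHKRPCFIPFPWRECSYIRIIRNMI
INNQMADILNNKNYYVSQFRCVFCDTTNCHANGLTIEAHLWRFMMLFVFYFHNPFFAMHK
WPHDFCTTPL
>cand_Hop2
SDDDGCLRGRYIEMLPKMLLTRGLCNGWITVSKYQIRLKCITVEVIYLRPDHAPQILDEF
VCRSHEAEDFECHDSWVFKWTSFVYPHEGAEDLNICKSLTDIMWCDQRWYQEKMPMLICA
AYCYVDTSPLWQCRPLVDEHCNWLHNCDRNQFLPMDWNMKRGTWHTPSENSRLGQFMFPH
PTGGCLPFNWICHNAWTKTGFQKDTQPQTSWQLINDAMAPSLVVCTEWLKCPTPSHHQMM
NISVKNYQSR
>cand_Msh4
TPIFGCNSHPYHDTERTERSKDNENYWIPQGVWMNYPVIFCVKGPICTRSPSSLYRTCLC
QVAQTWCAVDMMQMMYKQCACMFRQFGKYRYCGSLVLWPDNASWQLNVSQKTQSAWPDLV
QFMKQRPFNNQNRKFMMMQREIGMKCSRGAASHQMCYNGMVMVTKTQANCNNNRVTGSWH
RNSNPFYGPEDFNVQFLLESDSPEIENTVDVEANHYMMTEVWYIHTPFNVQNDTWQEFRT
ADRCRMYYHV
>cand_Msh5
NMYTCIENEMNDEAEGRDNFDYWFTENNKVWPYNNADWNNLEQCVKITRRFHKDYHGGMG
RCPGPAPIGMFRMQRKFMAGECGDQRSDRHECTWYRTHCNYSSKALQVYYNNQNMFSAMP
DLCHWVNSTCMWQVWYFHPNYTRLEPRQEMKLTAEYNWSLKSPPHKSPKMPLCGHCWTGP
TWMNFMDEHKKISIYHYDPCNDRLGRQHSNRLNDYEATQRLTYNEWWKNYRRTITCSSGR
PDTCPEMMEI
>cand_Rec8
SSTIEQGCQMQIWCNFTGCCKKLMWQLAFSFKAYLTYHDWIWLHICEGQPCNRYCQKYTW
WHFVMAAAHWMVEKMAPTQIWMEGVGVITPRFKHLAFFYGVCELYHKMWTAPWERTPPWR
DASRECMEYWANDYVHSFLLDYRMLMNSEMMFPEILIWLCLNNYCMIKCPDARGEWWCPV
LKFRIEHEMVGRNHLVKNLAEENHRYYVASKNGYDTNGAEGKIAVMMKQACCWQTGRSWW
FRTHSNPDWG
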