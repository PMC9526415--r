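>IS3|synthetic_exemplar
MMLTNTLVSDEFYGEAADKEKSNEYSGRWFPGVLLAAIPETVEVPMLGIRTVVYRDREFPTGSMLLASRQ
RKNGLSGWTQGENLLKVLIIKLEVAFDVQQTGERRFVLPPYHFAARNVPFGARRIIEEPDEIVTLTNLPT
NFYPSSARGFLLLHLYGQPVHRQRLCDFDLMATPLLESELLAAAIVGSEIDLVSEDKSCNSGYEHSNLLT
VYETLADAGGQLEVGIDRYVRVRWMGVISLAARDNVVGGLIKAEERLQTGADNAMLMEIIFVARVFTNGQ
GRAVPVFEEPAGIDVYFLHEPANQEERGLACAKKIKAVAFMIPKGVPRVH
>IS5|synthetic_exemplar
MDTIGDSIAGKRSRLAVTLTQNRVLFIPHVVQIKKFNYASKVRIRYGLVLGVGISDMAVETLLCDAIPSV
VHHEQQGRLFFQVFIGEGRLPGLEISYSPAFDEQATGIEEITLHIRNNPHGYLKHALLMTAYLLDVRISG
RAAGTIKSIGNRSVLGEESKIARGPLKIVIVYTVVMNLQPDIMPKAAPDFEADRDRKSVCARRRKACDPA
LMAYAWEVVKKSVAGPGGAAARRDEGIDLERITGALQSPYMIAGRDPLTGQPWALWVGLTGNGMNDNRIG
KYATPEREMRSNGENCNLPESDIVPNTRLKIVFALSLLEL
>IS6|synthetic_exemplar
MLIGAQRLHNVSGVIPVLARKGVAAARTLGFAVAMDANRSCNGPKIIKNTHTELVLPPAWMQGLSPWDEQ
DENDKFKLIFQINLWEPSSDKNLQDSGGHSHVEKCYICALDLEFALARGEVWDLTSQGFIAVNLDGTAMQ
FKLGQRSVTVVGLDILSIQAIGVETTGWLRDNACTSILLLVELQLTAISNCGKNPEWALTGEVGLIKKGA
IKYERTGSDKKPITSVLAGSYGPVD
>IS21|synthetic_exemplar
MMYLGNDFNTQRFARKKSEIRGATIDAHPRLGVIEEQVYGVEGETLKDAGAGMQRSWPGTIEASSAMEDP
LDLQGELYAQSTAYLRRLRKVLTKEREFRAARFLTKLVAERAHDDHQLVGEIGPFGGPTLVMAIAGGNQE
IKATEDEQFVLYEFLGNVVIINAGVLTMDMPPLIVEDKATYAKLVSLLRRSKLASLPKSEAEEVVARDTW
NPRARVLPLNKVGQKARLELGWLFPNIAEAYAVIALHRNEDITQSPEGVLSPKTRKYGLAEEYREKGAFI
ITAGGGNAKAVLTETVHHEAVEYSDSWFRFAIELVAHTSPNNDIDPVEMGGIERQLLTERQKAKRIAFRV
REAGVFLLIEGMSEVEPSRSVTDGSSKAEKAYALERGALDGFGAEWAGLT
>IS30|synthetic_exemplar
MIWPGTQPVGANAPEQKLKFCIFTGKLVIVAGTMLIYHQRGEGNDQKFYEPTEKAVSDDTVYRFYWCMEL
SLLNVHGGDQHSGPGGPNNKDSTEGTNDFYMREVSAGGRKAALSGLNAFQTWVTAFELGPYSSWAHHYGN
GVRALIGKLQLFQREWIAERVFEQIVHLTPEGYSNAIELLTLYRGRRSYGASLDDLINDPSHSKVDEGGG
ICTVRIVIQKELTTMRREYVGPWLPYAVMFGLGHEWNITPFFEDVKNDLLTSKLNYDDSFHKDVRLDSLS
GPTPTQAARPSGEVLMMIVT
>IS66|synthetic_exemplar
MSYNYYPFEDAICPVAKETLDKPSDLGDQTDEFDGANFKTLLTNEGILLMPYKCITPVQVLTPTADQTAL
TDALIEVSRHNKFGIGSPFTPNEFPRPFALAFDVHVYRVMWVRRAIATYMESIGKNNAAEPGDQLIAMPE
IIIEGVIIILFPVVYLVFEVSVSVDTTPDFWRKKGLDVFDYIETIGPEGLLPTTVATKDPVRKRNSILGI
DRACDFLMRYDHASLVIKDTEMTRDGFLRYIDKCVEGHIRRCTYLGDNSHDRLAVGRNGARITDPQRVEF
IFDWAWLSFASRIAGLEGGRVLIPTAFSVNEAFTELNNIVPNSRRGTGGVDSYVDLLVFGYKSCRWAAIL
AKVSNLGSEYPATGVTKGVGSPKNLYIEGRIDSPQLLFSVDIMVNAPPQKGLKEGTYTGIYVGPLKLMLA
>IS110|synthetic_exemplar
MVGMFGVVVYRSTGFAKESWAPQFGEAIIGALATNEKIMGNFTGVKSVLFYGRILPPMSKWALGKTDALV
QAAVTDVMDFDDSGSGPVLECDIRIGVGPDDNVNEKPHLIQMPKRRFTARLALSFELPDFLTVNASCLRH
DNEAFGIAGAFGLVHSPGAPANTEDAARFDDMSTLLKLKVNVTGDIPHEGLLAKAREWAKGRPMDYAQLR
YTLQLSECGALIRLTERLFPGSDPYTDFEKEDPAEYTKGTQLVVIKIKFDFEGQAGIREGIQIAGIRHNG
TLFFILFDAVPVLENLKYRRDWALVETDSKHSEPMKKNLAGSVLVPRVTIALMSGGIAISIEPNAALDHE
HNVLSDYWNWSAEFAGFRGLDFNMRRDIGP
>IS256|synthetic_exemplar
MLERSGPYGDAVEARLLATAYSWGVSLATTVQPSKASSKKSAFVEPRVIIGSWPVKFEHGRIGDFYRYDL
LHSSRGLGIALLNNDIGLGIGAGNIRGALTLHDLYYLTPQGNIPNADLPYKEGYQCLLAPIGGQGTPFLS
PIHNLNHHDNSPGGVYNPAEWDAVMEYMFGYEDNTSYELWQDDYARVILRTAEEDGEGLLDERTFLSVTA
TIGRQVILHLDDKSFGRSDEVAPRKVPTWLPNKACIRNHPNGETSVFTGAGEEKAYIATKGASQTSSSPL
AGADMVRLWLRDFTPIVAHSEVLGILEIQTVLLEGLSYQADESFDEAVSDALRERSYINNTQRDSHRRIS
KHSALGLICGECASTRYNKVTFNPDTLNSAAVDGRINPNK
>IS481|synthetic_exemplar
MLEMAVVAEFPEKDHEYPYFLLHYAFVEPLNGHVLIDTYTRGKDGIERNEALIRLEINYYHLRSSGTIST
ARIDQMAPGNSNKNSIKTNTFGTGIETDWFLLIGKYYRPPTWTERTKHNKSHSVDNDSDNQVCQLIRGIE
VITGLELGELGLLPRTVIFWDMTQSSSDESDDFISIERSVRLSKSEGVTVFTHGTVTDGNKDLNILGMSA
DNAPDLADERAKDFYGSGAILLDRSKPPKREDFNGIAEELTSPFQFTNTFTPDFYNGIESGLVFFALLSL
MYVVHHAWSA
>IS630|synthetic_exemplar
MECVGSEGFFLYKTQLNQTVVIGAPKARTTMKHELKEHLNVGSGIGLKVNMLEYLVVAKASHDGINRHVG
EWKAVRQAGALDAVMLNLPDRELALSVDVQEIVGIISLSKTTIHKGNNRHALKSGDDYGATLGAENYQQG
KTSLELKVTGEDVTTGYPDRPVYTHLNAVSCGSFNLVITSYTAANVAALPLADQKGPEELDLDPGSDVAA
EASSVNADIAPGTAMQLSTTTAVGGGNKDGKRVVYEFIRQSAGPIDAPRPESLHHRLQDGPPTHVDEFRV
GSATLKITGTKIGEYVSTGDIRSGTPGNSLYLAFFAQQGGNNVVGAYFIGLLRLKLTGVNMNRIA
>ISL3|synthetic_exemplar
MMSGAKEGKKIDGALIETAAASGDGCLNEPRNTGADVRTPGITINNGVITVIGAYRDVYELHEYQPKDLK
VLRLQLAETQADLLLPPADDFVSAAQAYRTPSIQPLKFSGEKLAPHVSVRQEVCEGEHRSVFEGVVNPCI
SNGQSLGSAWKGVRKVDEGERVRVASDLGYMIAKLFRVKPEIEEVAVASVGIGENKLTLRLEIVSDAASF
GFGDTIVCWGDIDVGKRYGVPTILTVTASRFTGEDFGMKTSVKKAYQGDSMKVKTPFYRIKSLEVHYQCP
LFAPDPVPATCDHWPMTKFTIVEHTFQAWRIIFLDSALGPNRVNAIGTYLKDLDDIREVVVTWKRPLKDE
PYGLEEARCMEATSHPQRVNQKEDILRLDTLNFGEEQGKRAAQKLFAIGL
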