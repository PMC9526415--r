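>alkB|synthetic_exemplar
MDSVVIENTFPDTDDNNSLFMKILEVFWPDLNRGDIDNHALAGTVVAQTKVCSYAEAAVIGFNHLFEKSL
RLNISRVNRALVLIDPRQAIYLTRQMCDIPPYDSLQTSASKPIGMNYSIRQDSLTVYELPKQILSDVNVD
SSLPTRRLRELDKSAHARTISDEVQSEYARLLLTFAGDPDFAELCGAHGLVIATILKDYADGSAGDKMTK
LGAGGMGSRANTYPALGDPGATSQDAITASYGSSAGLLVRDMSGILSWLKRQITEFQLSQEPGSIRAGGL
RLCEKLGLCQTSVAHRASGPVPVDSGVRVSIDEKVSQNHSGIKPDIGKYIAYGPYLTNDIRGYNGDAPQE
PFEVMGLPVDFTQRDIPNCPKQVINGSPLYPGFTQMLTATFADIVKLIPFI
>alkF|synthetic_exemplar
MDKKHFDTAAAGNGVIGGYAPKSLYISDLISPDERPNFDLAARVKDDNEAEDRKGSDFACADAGDIRELE
VGSLLLFGERIGTDGIDLIQLADALQTAVTPTKPGSYLFHFTIDRAVDER
>alkG|synthetic_exemplar
MEFWRSATCYYSKTTVDKGGVAAFYKYLEECLIGHEGLPANVLFLSPTEDKAMVSYHSADERLKHAWNYL
QVYSYLSLCIKTVLVIMNQTSSLGAGLTHFMESARSRREPRSCVGGGQKFTAKEVESPETINGCGYHIKR
YALEIKMQQRLMIYQSDANVPLFIITGEND
>alkH|synthetic_exemplar
MEPAVASVTFNLEATDAIEPSQTETLAHACLVLKFADGKYRGSERLMYVRGETLVHCRLSAGLVEVEYTR
PKMQGNTAPKKNEFPLLAAQPTEKTEGEGWNSPSFIGAPDNAANASLSLKIAPQAQADFERIIVEYNKSP
GEVVTFQIPTTVQGDWSPEDGSDLTGSSEELLPDGADIILDPIRPLVVYYPFGLVLEGRILQLRGITQHA
YGKMALGLLYLGVNHYVGGILYLDEISNHEVSALELIMDQILVAAKASHATLVAQLNLGTIEDVRGDNAL
KELNVRPVHGPGMDQSGEADEAAPERRHRNEQVPLLRGWHQWYLARKIVDHLIACAGMLLTDLLVAQGKG
KEKLIHYDAGARPPGVGEKTLAERNATIICAAWGTEALASSSSFVDIPTVWGTIVTLDTAVDRFNWTADG
GKKDQNKHEKISEMFILQESWPSFGDTYNRTTTLLALIANAPEHNKTLPNLILNFRGSIRAMYRQV
>alkJ|synthetic_exemplar
MEGGDSMILLNRVDGITPSDRMNGICEVALLLIIPGYYDVGKPIAIESTHLAQYDSNVAPRVFEIPESTF
YSEGIQIAEPSLGVTKFALIEKHSDTVMIPCGNKLMVQAARHHNRTLGVARHSLEYAVSCLMMIIMCFYM
VVEIYTAPAGQDLPSLFAFKVTAVAQFSTTAQHLEIDALKGNIGVVNAHTLWETKTKIELLGIFQGYTLI
FMAGLETAACDPREGTNIRSEIGFAVAVLRSKSSYSERMRLAESIEQGGFQKSALYSVNSTDKDMCKEEV
GAAIAQDTDASETLNVDLKFSDVSGAASGHVDLFRFRRYMGEVVEDDAAEAFLETQGGTSFAAKWRTPAE
DERAAMAVAFASITYLVQPPRVDGKRIKTARETLLKSVAEKLSVANKHQSNGLLSANKAMAAADKIEAGR
MVWEIEDPDTIWGKLGILGNMDSWLTAQWVRITDKSAAVYLLVPPLFILVVVSAKFATFAILDLDSGLII
SVVDVDKLHECAHTYNPDPYIQSLPGNPDPGAEDGLSICGFVWESGPNAPDGTDPELYMTGASGSEPY
>alkK|synthetic_exemplar
MAPFIVAVLERRKGMVTFLSVNLEPLEEIKHHTRTPMTTFWRGSIYIHWKPAATKTNSVIAWQEAYVDQV
FTRSLALSIKKRETYESVAEPRGMGRGLRATAKPDYKVGSELGIRGQAPLTPTDAPEVTQRMMVVGTYTQ
MNAMNLQAADIAPSTCGIFTRPERDCRLISVGTLIAPALDEKRATRCLEGFKLLAWDKLLRDRLLKLGQG
NEVINGAYFQRTMAPCAHLDAVSLVVIVQLDEERRAEGLKYKTFHVGLRPLDMARKHDKHLIFKIRCTKS
KPAIEDVSFQSDDTWDDLLFEPETSAAAPRGIRERMPQGRCGVKVLSNSGLLLENLRQFYAETAFDGGAF
LTLVSLAMKTTGCAAMAAVAAYRLEIRDASHYHKEFWFRRYARVFMLSPLSSGKNLIFGDEHTWNPDDEG
EACRGAGPVDLVDPYLIRTMPSNRLRGEGGEDYSVSFQVEDDLVTIAGASHGVELVALFDYVDELITVNL
NILGFAGLGLTAISSPELVRHKGSRVNAEDEPLPLLDAFAFTVPTPFQSVTAKADERA
>alkL|synthetic_exemplar
MTGTGQVEYPKAPNVSSRKVLAQQSAGVPLAKAERGRGILHTAHPKAIVILIRSENGGILHFQRQYLARD
QSMEPETGHDSRNLAELTLTTPPVLPRTLSIIGVYLRPASLNLVKDPFSALCQAIRLSFYVDVYKPPLYI
VAVQVHSDVHNTLRVCGHLDATMISAQQLGSNEISYPTLVPDFLIAYAYLRQTEERLDILTLVLHDHRSA
KAKQLAFQLEKRKLTAGVGN
>alkN|synthetic_exemplar
MDAGVMKGAFLVTISDSILRGAMLGIIDKTFQMGPNIAVSKNQGSSFALKVNNITWFLGEQLGCLFLKRP
KSGPVQDSMEVEGKSAISFNEDLAENQENEIREANQDDVIVGADVDSAAPINHVWYLHVKRNVSAGDREL
PITSFDNGSIKAGEEPIPAARRAAMKCAYIIDYALDMGTIIDKNSLRYPLNDKPPVFVVDIAGPIATLLR
YGTTQQQPKLEGDETSEACWDGTHNSDARTHIETLIRWPVAANVTSQLAMTKALEFDISNIGPPIMIMRN
RCGWFAKTQLNKSVTYKDSLMVPICLHDEAIKQMPLHLGLPAKQRNDEKGYLITQDSNRLVARIVHNEIE
KIKEEGFLHEVIDFWFFPVDNAGGAVVTVVRPGADVLPLLFKDFTSVGREDGLHLNGAKSTNQPFTFTQT
MYVAGIAKAR
>alkS|synthetic_exemplar
MPVKIVQHSYPDPAGYSLAISGLFPVISEQYHLEFPILRVEKIKAGDPVDFIMNERVSFGAGLIMASRNI
GTPPRDGAKIFSALPCELVGTLVGLDGESHLNNRLQQETVGVDTWLLLNRFPRELVFHKSYLGPFYLSGR
ARKVYYKVHDDIAATAPKSEFKPLSLVGPTFVPVSQTFRLGRAKLQMIEDATADKKAAGESKTGVFRGLV
EPNEYEVFSPIVIGTIVPNHYLADNIIEAEMLTQTNPQPDDKPDLDDTMTERWLLNLEQEDPNEDAGAKQ
HLAYNEDYMWPQAGEIIMSEGSAKTSQLDLLTDLCAPWEPALSITNIDDAQWFKLPVLDKAVSLTEVWAV
LMIIVVKIKIAIGATLNFPRDVSMSMKSNKKPMLAYKTAEEDLLTDVALHLLELGALPAVIVRIGGGTSD
DRPLGDRHFKCVLYLGGPLRFVLALDLMSEDGYYPLLVMVNGLMGMNIEPRTILILPSLGQSSHRTSSHQ
FNGFRVTARIAMFFLFGPLICYSCEYETQIERAEGEQSWVDGSGEPGTAVCQMKYARMRLSIGLYSQLRV
IRGMDDLDLRIGNNVHVAESLLVLGSLVKGAKEFSVVIDLYISRLRYRLGAQERWEDCATGGVATPFSLV
FIDSPRASNE
>alkT|synthetic_exemplar
MFLRDGAHIGKWMANSACRRGPVLETPDVVNDKGADSNRLGAIYPRAANAVGAALLTDQTLRLTGADDIP
KPKINQRKAHGRANRFVHAGSGGNNSDDAKEKAGRAAERGVQESCETPTTAGRNLQIDRNTLTPNCQLAV
FTHPEIGKEYVFYGVYKSKAGVVASLQVCLPCVQGGEAAAANALLKKGDDLFDPPRVDGGFGQDDVYRER
MLTLIICCELVGGDWLARRIGVLAPLRTKALQDGPLIRNAVLSDSGLHLKDQDPGEGVESVKDTALRMYM
LGIEAIEIALETLRTGQAENGLIFFNVNRNAPRADNEGRIIRTNVKANDPSDRRKDGLRIRA
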