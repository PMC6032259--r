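>AQP0
LAMFLGNYFWGEEWVLHCSSHVVSDQFWYMCNGKEAHMMARGRVDSNLCPTDKFLFSLGYYVGGSDGNAVFMPTGANTAWRQNCACQAPMSIGPWVNALRQRQFNCRCVQHQYKLSKMPCHWKNSWKFCEMVISNPWVRRWERGRWPRMMSDMISDNKGPDDAIHTIRTWFGKLFCGIMGIIMDRMRFQSRNIPMQAILDYNLGQCRNFDVWFANMPSLCVAHRTIAYTMRQRNMSWHQNWWSNFWLHDFLKDKIRGSLR
>AQP1
VFRMGCPSTRDDYKFRGPNALLASLQWKFQDISIHRAPSTKCELQWFTLWYCSFVMRSISRGRGWCKNYRQCYNSWKVDDDGMNHCSHNLADRRKKSEWHIRSHWMFAHQKLNKQATEKKNQYPSKTQSPKQNATHPMCSECRHSFDTQHYSMANMCYMFLMFCREPERVKDCFGDPWPGWNWLSFRNRFSRDKGVNGSVMFLMWHDWVQECILMWDAFMRSAVVHLQTQFGCDMWVHPQWSCDSDYPMMLVSYKLVYYH
>AQP2
WKGVRPMHYTSCDNMFVQNDTDTWEEDCCWQPLPIYMFEWCTVGAKKWQQMWVIGVNFNQYHHGYWENTVHGDQVSAKWFYRCWIMMDQDVNEMSKFKWVNHPWDDMTFMFRNCYEREGGNEPDLHRNMDCYLEFLIWHWYWDRYFYSPYERRQDCSWIRSKDLSEWWRVEPAMWGLDQGAWYQIDREGYKRGSMTENYCRCWPYSHAIHNCVHVVFWDLSGSYHNWDSPNGEYMNNKYMICTEKPQWDNFMRVDVNRAW
>AQP4
QTTWYNDFIMAAMEDFNWFNAEGERSKMPHLEQNFSSTHWVADMPADAQEPFVWIYWFGMLKIGNKANILNSVNGLFDETCMPSPIYITHSFFDLPYGARKVAIHDNILCYCIRTFPEAKFTSKMELTMMKAVVTVPPIHLWLRSRQMDDTMWAYMFHENISTMLCSTYDTTTNYIRMVGPCHQSQRLQMKTMKAEQSHNVCNLTNAQIERIMGLYNFMCGFFAQMRGNERLRNDHNIHYAQQEMGLYLTLCHIQYFLPD
>AQP5
PNLCNRSDNMHPQKADLKHVYSRDAPWMFMVGPGHFDVRNMTHFFVYVKCELMTSVDQIWLCTGKWVNWERAQVFYVSDYKRNGNFHQGWVQGIFQRWQNIQWALRIWYVLEVGCVLQIRCHKYLMVFWRKGRRTRHHVETHQKLGCWFEPELVTAQGWCLCEFHLEITEPIEVDSITMGNTAKQLRLHHGLIWQGAIVSHKWKAHHCSLDKHRNPQNNCYSIGVSTNFPRRCKAFPAQPNGTAIGCKNSANFKKVSWSH
>AQP6
KFKMNAHHQVCSGFDNEYNIHDMEFGRARWESPCECYYKPGHYLNHWMMIQFHRIKSPAWLRFGWMCNAFWLRCQRVLMWQVCYCSQQLGVPYNDVFYTKAQPWIFIIYSPAWSRRTGCYAEAGYHYVCSEPSNITISLTAEVVTKDHWNPLLGISWDLLELVTPWAYNFHRNAKNIFPGRSQCYKRAINYYSLLCGIHYAQYFGNPETYAVNVIMRTLMRHSWVQAWFRPLPPNKDVPPEQTQHLWGKRWHGAISVNLM
>AQP8
---GCLGWYMYDNQSRVQPAKKQQGTLCETGDIGYYAHVMYKAWHNFAIGRSILIEWVENRCRGAYMNQPEHKKYDTNRFSQPDEDTWCTYLVDRWKEMAHKAVLHCEIPVYYGIFCTVQDCSIKPRCGFEGPPSHQTHPAFWTVLAMDRSDAPHCINVNQKPAWKGCFGNYDPLTWECGVGNCMKRNAFNHTAFAFENIRDLMTHVIACAMQGENQASNHDSERHVSCRVQRVGGIGDMEEPMACAIAMHMYIAYAFFV
>AQP3
NDPQWMCRQGTLWWFLIGSCSCRNLPPQNAWIPVSHYERIWHFGNMRIDIMQVMFRGKNLPQAGSYNNAHRNLREYQPDHMSYLSMAHICDCSQDFDSVTASHVVNRMIPGEGETHDIHQSWPECWHNRCDTDWCKHMNLWNVQLTVMWHPEHCWFDPEIPSDANQACKAIILEGYIIQGGWVIFNRQPCFKRFQAWTTQKQHFHIPVSFCPMAMNYDFLQGNMLQDNCTMAGEWSDNVVCICFYNHQFVDRTNQKRDVD
>AQP7
ASKMTAIVTDCVDSWVFAPHCCCSINDFCQCKWCGWTEAWMSPCSDFTYLPSFMFADQPAVTLGQCRNNRMISPRILTQERHHFQQANKFRMEICDRMWKIAGIEVHDWSIYGMYDYVEMEWEPLVRCWWHFANGCSQSVSINKRACMAEYKELTPPMWKWNGHHYPWQNCSCQFAHGEGDSACFFRIAKGTHAYAKDNHNWDDYGYLSMPEKIFQAETNPLFLMANFGREGEARVKHTMPAWRICERKTNLVMILDVKD
>AQP9
GWAWADSPWQADWCRVARVVPTGSDLVSVDIPHPIIRMSVDWRTIIDQFETWGLPSAGKQFKTGDDSNITAEAHQVKIWCNTLTGTLMVPNLCQFPEWCALIPGAVYKWFGPWGDNTQCMRYQTYQNFDMWLVYPSFKRGPLMRDVKNQTTNGRIDEMLCYEIWHIWVSVCCDGTGQRVGQEQCAGRTVSRDFNNKHNIIPGPYYVWWLGLVNEIYAHWKMNAFPLFCTTQGGDYAHEASDTWMQSEHYPWWQPRVQHTW
>AQP10
IAWLHTHHYGIHQWNDECHMGRRGCDNFEGMIEYRIPMPEVQWHHDAMIELYYEWPINHMVHYGYCCNHENSGPCRVHAIFFRPTETQACRGTQNYGDKFQCCFKHRTRGHDKRYTMSVCDHSVWKRTKRCQMMADEGSGLNTALDAWDPFDPDSIRTYTIQWHWLANELQLYSCMWQVGFVETWNRKRTGFHACTTFTFALFMVFWHGMHMVFNGCWNKGPLAIPDMSVRCQACIISRRGETGIYNKNFIEKWVAHSSN
>AQP11
TDHRTRPQMKDNKAHCKVGFLDASKMWKCCASPYYFHPYIVLRKPWGDECVEWGRHSCFWIWHGWCMNPWWVEWAIMLIVRLLGFPWYNQFQWGNFTWPSETSWYFARNIDESHEHHDAHCFAIFYQQNLVINYWWESVQGKIKILKLANDCSTIPNRHYDCNCGQMAFNLRNKIEHMWGIFTVCCRPMCGQKFVYVYCTFADEHHYYGYWEQTHDITNCDNLSTVHRDMQTPDASNHWF--------------------
>AQP12
KDRIIGVFVRKGSDYQMQDPVLKMSQRHGFIAMWIQAPLLCKGNMTHPIAPQNLGNASNGMAAGGEWNFYETGCEDFMYGKAGYNMLLVPFKWNRHSGKGCAYIPDGWPGREQAGDTMFMIQYFDVQCYVQPVVMFCEGHVSCTSRWETKRKGGKKRREHRDSLNQLHFRPFTEMCTEWGCLLHAFRGQIAWNFIFDHFAEAKMVCNCGPTNTIHTNQKYCGIVPVTLGLKHHNTGWITP--------------------
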