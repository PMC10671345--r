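; SYNTHETIC archetype stand-ins for the 21 leech antithrombotic families.
; Not the accessioned reference proteins: deterministic constructs that
; carry each family's documented length class, cysteine scaffold and
; internal tandem-repeat structure, for simulation and testing.
>hirudin synthetic_archetype
QLCPKQAMPGDWSKCEKIDSNARNDCPVEPSFNNKEEGCHAVQESYYVIVDCFKSVIYATFYLCF
>granulin synthetic_archetype
HCYYRWMMCSPYVCGEFCMSVMRCNIRCIGDMTCKQRCIQDCENRAMSCDEVHCFEELCQHCYYRWMMCS
PYVCGEFCMSVMRCNIRCIGDMTCKQRCIQDCENRAMSCDEVHCFEELCQHCYYRWMMCSPYVCGEFCMS
VMRCNIRCIGDMTCKQRCIQDCENRAMSCDEVHCFEELCQHCYYRWMMCSPYVCGEFCMSVMRCNIRCIG
DMTCKQRCIQDCENRAMSCDEVHCFEELCQHCYYRWMMCSPYVCGEFCMSVMRCNIRCIGDMTCKQRCIQ
DCENRAMSCDEVHCFEELCQ
>antistasin synthetic_archetype
HKCPEFCAWYYCDGSDCLGFDCAFLWCQHWESHCDMCTRHWWCYFTICKQHKCPEFCAWYYCDGSDCLGF
DCAFLWCQHWESHCDMCTRHWWCYFTICKQEFPTPQSF
>lefaxin synthetic_archetype
DYHETTIGVAHREMHRNVIFLKIRQPWGWAVSYMKGSTWFGWDSWMPLTIISKAVTGLQHGRSDTNQTKP
HMKWSSDKIRGAERITWSEALISKYSNSIG
>therostasin synthetic_archetype
SCTGQLRNCFACFESFSDCKQYCRHMTCQEVACEVSDNCQPTTCGMCIAMWAPCRHGCLNSTCGNQLCVL
GICKNKCERA
>hirustasin synthetic_archetype
HGCRTDRCTMTMPCNQITVPCVECFDDLHTGCVRVCQEVKCRPLWQCHIKGIFCP
>guamerin synthetic_archetype
HGCRGDRCTMDMYCLQITRPCVLCFPDLHTYCYRVCEEVKCRPPWQCHFAAIFCP
>piguamerin synthetic_archetype
HGCRTDRCTMSMPCNKIYANCVECFDNLNWGCVVVCQEVKCRPVTHCAIKAIFCP
>bdellastasin synthetic_archetype
HGCRFERCTMWTPCWQSTVPCHECDDTLSTGCVDVCQEYKCVPLQQCHIKGIFCP
>poecistasin synthetic_archetype
HGCFTNDCTMSMPCNHIKVPCVECFDMFQTGCVHPCQEVKCINLWQCHIGGIFCP
>eglin synthetic_archetype
IPRRPTWMNFNIINILVTVWNSFYTGLQISHFSTPHSLQTQKFTGTTESVKQEIQVNFSHITLLGMKEWG
>bdellin synthetic_archetype
VRCKRVQNEFQSTWQMVAVAAHCKESFNASQEVDIFSHVSNNNACMNAVNEYGARMYVESNYWAFICERR
ANQTTHMIQIYGKYNCVIAMIDHGKHHPAIHVIWDETACI
>LDTI synthetic_archetype
EACEIQDHCKYVCRGQCQHSYCILYWWCRQYHNRIEACEIQDHCKYVCRGQCQHSYCILYWWCRQLEKV
>HMEI synthetic_archetype
PAICGEISVYFCQSERGAGCSVSRHRVEPCYHTMGPKSMCSKNAQCAEPFDSVQKLCQWRRLHICEKLTV
DSCKMPEWYGSHCMF
>saratin synthetic_archetype
MLCHGMQPMWWTNVLINKKIPGICNQSFHKGFYDMTSFARVCSHEVQWGLKVKYEQRHNTVKCTNGKVTV
PLRIDSYGSCMNSDWAYNANAAWPWASIMDDCD
>apyrase synthetic_archetype
QHCFTFREQNRRTEPVTKPLQKGIQGPQIWHNQKLWEFQWEIAKDFFTSMADFGRPVDERIYMNLNYYNQ
VHGSQPVGDYAGYFTRFQLREVQEAETYPYPERPVFTHHKWRQHVHLIRQEFAPSMDNPLKVKKVYTRAM
MSSKDHYVYTQIPEERVQNGIIAARYTWISQGIGYGQWHMNIYWERIWKPSYLNNFHLDNEIEKRHMFAA
SEREWYMRPNPQIWFWRTDGPIVDMQGHLIQPDQKFGTDWSWMSPTYSWPDTMSQAGNMTSERSEMSHYW
QDSKETKVYRFNMVNGNPPMTNRLKNFPIAMETESTQAILDMMQQKPGCM
>lumbrokinase synthetic_archetype
MCDYDAWIYYVNQSEQLSNKCNDIVLELLRFYPMLEHFCNGIHPEVEWPFDPLDAGCKEKKNRSPTHGEW
YKGCKHSGDPQMLMKETFAVNMQCQDIGKNDPTEHKMVLCKQHKYEQHGKSSAARLIPCFMLAKTKKAIY
TVRTRQQCYTHQLEQSMPNNSNTCWVKWYGEIGVHAKETLKCDLREATPFWYSDHQKETCGPDDYAWQQQ
SVYWWVWCDPWDFMPYYYNYLEAELCTWM
>destabilase synthetic_archetype
LCPWWWDQFTCLHMQGHSCTNDDNTFDPCKGGQLKLHCYDQQNCTYAWFSSNHQCRHQAMLCQGHNRLYC
EMQSKYQCKNGWMMTNAPCAFFGTVCNGFTWYMICEPTDRAMWCQ
>GGT synthetic_archetype
MQCAFEFWYARSQPQNQDEHAKGRPGYKLNEEDIKTFPTRDYTRMQHHREFSLPPQFDPWMPWKFKQKGR
FKPSVSCTLFSMFFDMYFAYWFGFLWYIVHFFIESREKGNEYPDTERIEYTEMFTWYLQMANKREFYFMR
RVTQKEFDVTHTLCFWGAMYPSGTAEDDPSKNKHVPSDYPFTDWNFTTLGEWHFYPGMKMEHQTQRNLFR
QWYNNVPHTMGMSEMQEPCESKKNLRKEWYYMILEHEVTHETGHYEQNVVHEFQTKQLSTWYNNHKSIAF
VHSRRFWFAYWTHKFHYQDPTSCDVVWPNHRKLSPIISLKEDWSYTAWHKKEQHIQSTWMAEMNFPERGL
MPVYLRGEKEFYMARTNWKHQAARPECHHL
>LCI synthetic_archetype
YLCQANRHHAWICAFSPGSDWCQGVVWDQCPETYDLNCMVEVVTATCLDPTASHCTNMQFDVIVCWT
>hyaluronidase synthetic_archetype
YCDRQNIQYNKPFPGLGRGGSPMFNLYPFFGYRRLEYWPRVVVWIMVKMAPEWVRNNENKAKWQKTGIYS
SPWEEKALLQPWIPAAEQAAPQRFWLGSSDMKQTRDAWVLNLTHHSQWIMFNIGVKPWDDYRWERMDRIT
IDLAMMWIYEAMSWLPVGNPWEMISPTIIMHVMLSQSWLTSVFLSFSKWDPWRMRFLWKAPAGNINNREY
LWLNFDHFVITKGPRTTQANGMINPYYAFHPGVFMFSQWIEKSPWFKFYYSLAEMFQFFLATIYGPHHFW
GGFDHYTPMAHNQRKRRVCG
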