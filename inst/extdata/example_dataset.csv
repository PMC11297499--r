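peptide,A1,A2,A3,B1,B2,B3,binder,partition,origin
IDIRINWYIV,PELHNPH,PEIDQN,QQLYLLADKRAD,HGRSW,KVTMTMTK,GYFMCYFTSRKPQ,1,1,synthetic
IDIRINWYIV,WELTG,QFPDWMR,FHMLDRAKWVLSHLW,SKHKVQW,VIKFPTV,AALMCYIIGFGVITKY,1,0,synthetic
IDIRINWYIV,NQMKIAM,TAWPMGL,AKHETGEFEV,KYHCYY,APGASAC,WACMCYKRDLNTM,1,1,synthetic
IDIRINWYIV,LVNDRF,HSGCQHDV,SRKCYHAASYCKLTY,ENETL,HDFAVAW,EECMCYRLEGVWYW,1,0,synthetic
IDIRINWYIV,VCAMHC,LVNRFEQI,MKTTINEPLWCDLAR,ESNRN,QGECNNQS,NDDMCYPRDKKQPPVP,1,0,synthetic
IDIRINWYIV,AGQIR,YTSQCY,MNFCLRDNSLECAVP,QDLPA,ESTLMASV,YGNMCYMGEHWCDDI,1,0,synthetic
IDIRINWYIV,RCRMED,DDDCEI,YPPLQPEMMNWPHY,HIAPLF,CPTQTKH,HVMMCYYWDWCRFP,1,1,synthetic
IDIRINWYIV,CDVIP,RVIQCSTT,MREKLHALTWCRDQE,VGYTE,RCDFES,CGYMCYYIHGLTEHV,1,1,synthetic
RGSEMGCEGMI,NPLNWM,ITVGTS,MIAPNMNKACN,DFIDTM,SLSRENP,TPNCVIHKGEFCLDNV,1,0,synthetic
RGSEMGCEGMI,NCKLES,SVHTGY,DEYGKYYNDIGCVYG,DPMSPH,DNYVPSY,ASYCVILGIRSQYI,1,0,synthetic
RGSEMGCEGMI,REMAV,RQWTHF,HEMWSAWNCMCFIYE,WTLYPFK,ARCKTMSA,RSQCVISWLWGFDEQ,1,0,synthetic
RGSEMGCEGMI,AMTPV,NDYPIDMC,VFERTRSLGLV,MLQWG,IPHNVNGC,GCQCVICGMVELK,1,1,synthetic
RGSEMGCEGMI,IFWNC,LMQPGN,PWYSFHTNPSR,GDHENA,CWELAYT,WPICVIKRMMTNDDV,1,1,synthetic
RGSEMGCEGMI,PVWACHR,HQPYYY,WDMPMHLHTN,FCGEMI,MFAWFRM,IMKCVIDRNWYSTV,1,1,synthetic
RGSEMGCEGMI,LLIDFLN,PNQNTQD,KYALSWEEKMLHHCQ,WQSNFSM,KASFYMLM,AHICVIEQFKYRPT,1,1,synthetic
RGSEMGCEGMI,RCHDCYK,PRPHCFHS,SHNPSPMYSCLSWRE,SYTEYEC,RTRIQG,KIPCVINGHCLQCY,1,0,synthetic
TQEDPKIPRKC,WYCIY,FYILGR,KVQQAEMGLDCNM,KAVWGM,NGSSRS,RCLFTSGCKIPMLMA,1,0,synthetic
TQEDPKIPRKC,SSCHW,KKISSPD,YLTQWCQHICNS,ACSKESC,EKFVAEG,YETFTSKYSSACMTQP,1,0,synthetic
TQEDPKIPRKC,SMCHVNG,FDAVLIVR,TKGRSCQHPSF,RNSAWK,LERKVTA,CDYFTSLTTPLC,1,0,synthetic
TQEDPKIPRKC,CRWSIC,HQGKMS,YTSLECHDFR,IASRWK,DPVKPD,CPLFTSLDPQAQKAWA,1,1,synthetic
TQEDPKIPRKC,PEFFMN,LESSDQ,PPVQPEQIYRGD,SMKFMSH,LKIKMQK,AFTFTSNKSCQRQYN,1,0,synthetic
TQEDPKIPRKC,GKFWASI,GLWCNGE,PELDALMDFTKSE,PACSPMH,MDYPSKIE,HKDFTSSYHNCTM,1,1,synthetic
TQEDPKIPRKC,LASVT,WTQEDH,WPQRYNIYQKPIY,GFSPG,DTLFFLM,CTLFTSEWRQEPS,1,0,synthetic
TQEDPKIPRKC,FYVHY,QKNKDK,SIWWLNIVGHR,AKMMLI,DNYVIDTH,TGIFTSWFKNEQHCEE,1,1,synthetic
NILQISVFGDK,TVGKK,LRFGEIYN,EDVVPTIWEEFRG,TVKTW,DEMPNDW,CKMKRMIRHHSRLQI,1,1,synthetic
NILQISVFGDK,ACYPW,HLFFAF,KCDPCNYCIFRRTLPG,NRWHE,HLILCT,GKQKRMAYVKDINQ,1,0,synthetic
NILQISVFGDK,QNWKYPD,MNMYFMLN,KFENNLNAVEKHTWLS,HVLTS,VSPDPLHN,KAIKRMFDSMNDNIL,1,1,synthetic
NILQISVFGDK,WDDWF,APVWAQ,CLSAWKLDEYNVDD,PTMRF,YIMMSF,TFPKRMLAWYFEI,1,1,synthetic
NILQISVFGDK,HCYTRQW,FYCFQHE,TDQYADDGYTE,MMWSMRY,PCRQDN,EPKKRMNHPAQEWFD,1,0,synthetic
NILQISVFGDK,MLGPQY,IKWWGEM,INMANYQDLPLQRF,CWWSILV,SCSEHPHI,SPNKRMDGFPEAH,1,1,synthetic
NILQISVFGDK,NTPKD,NWMQSS,DPIRPIKKHSLI,MRSYSV,PHHDHQKR,WESKRMDDYNASPECS,1,0,synthetic
NILQISVFGDK,LEVSFSA,PLPTWG,QFICSKMHIFYWK,MDICD,KSMNKADT,NSVKRMVGTMFPAE,1,1,synthetic
NILQISVFGDK,IFWNC,LMQPGN,PWYSFHTNPSR,GDHENA,CWELAYT,WPICVIKRMMTNDDV,1,0,synthetic
TQEDPKIPRKC,PELHNPH,PEIDQN,QQLYLLADKRAD,HGRSW,KVTMTMTK,GYFMCYFTSRKPQ,1,1,synthetic
IDIRINWYIV,SSCHW,KKISSPD,YLTQWCQHICNS,ACSKESC,EKFVAEG,YETFTSKYSSACMTQP,0,0,shuffled_negative
IDIRINWYIV,RCHDCYK,PRPHCFHS,SHNPSPMYSCLSWRE,SYTEYEC,RTRIQG,KIPCVINGHCLQCY,0,0,shuffled_negative
IDIRINWYIV,NTPKD,NWMQSS,DPIRPIKKHSLI,MRSYSV,PHHDHQKR,WESKRMDDYNASPECS,0,0,shuffled_negative
IDIRINWYIV,LASVT,WTQEDH,WPQRYNIYQKPIY,GFSPG,DTLFFLM,CTLFTSEWRQEPS,0,0,shuffled_negative
RGSEMGCEGMI,NTPKD,NWMQSS,DPIRPIKKHSLI,MRSYSV,PHHDHQKR,WESKRMDDYNASPECS,0,0,shuffled_negative
RGSEMGCEGMI,HCYTRQW,FYCFQHE,TDQYADDGYTE,MMWSMRY,PCRQDN,EPKKRMNHPAQEWFD,0,0,shuffled_negative
RGSEMGCEGMI,VCAMHC,LVNRFEQI,MKTTINEPLWCDLAR,ESNRN,QGECNNQS,NDDMCYPRDKKQPPVP,0,0,shuffled_negative
RGSEMGCEGMI,ACYPW,HLFFAF,KCDPCNYCIFRRTLPG,NRWHE,HLILCT,GKQKRMAYVKDINQ,0,0,shuffled_negative
TQEDPKIPRKC,ACYPW,HLFFAF,KCDPCNYCIFRRTLPG,NRWHE,HLILCT,GKQKRMAYVKDINQ,0,0,shuffled_negative
TQEDPKIPRKC,VCAMHC,LVNRFEQI,MKTTINEPLWCDLAR,ESNRN,QGECNNQS,NDDMCYPRDKKQPPVP,0,0,shuffled_negative
TQEDPKIPRKC,NCKLES,SVHTGY,DEYGKYYNDIGCVYG,DPMSPH,DNYVPSY,ASYCVILGIRSQYI,0,0,shuffled_negative
TQEDPKIPRKC,NPLNWM,ITVGTS,MIAPNMNKACN,DFIDTM,SLSRENP,TPNCVIHKGEFCLDNV,0,0,shuffled_negative
TQEDPKIPRKC,IFWNC,LMQPGN,PWYSFHTNPSR,GDHENA,CWELAYT,WPICVIKRMMTNDDV,0,0,shuffled_negative
NILQISVFGDK,PEFFMN,LESSDQ,PPVQPEQIYRGD,SMKFMSH,LKIKMQK,AFTFTSNKSCQRQYN,0,0,shuffled_negative
NILQISVFGDK,NCKLES,SVHTGY,DEYGKYYNDIGCVYG,DPMSPH,DNYVPSY,ASYCVILGIRSQYI,0,0,shuffled_negative
NILQISVFGDK,LVNDRF,HSGCQHDV,SRKCYHAASYCKLTY,ENETL,HDFAVAW,EECMCYRLEGVWYW,0,0,shuffled_negative
NILQISVFGDK,WELTG,QFPDWMR,FHMLDRAKWVLSHLW,SKHKVQW,VIKFPTV,AALMCYIIGFGVITKY,0,0,shuffled_negative
IDIRINWYIV,FYVHY,QKNKDK,SIWWLNIVGHR,AKMMLI,DNYVIDTH,TGIFTSWFKNEQHCEE,0,1,shuffled_negative
IDIRINWYIV,QNWKYPD,MNMYFMLN,KFENNLNAVEKHTWLS,HVLTS,VSPDPLHN,KAIKRMFDSMNDNIL,0,1,shuffled_negative
IDIRINWYIV,AMTPV,NDYPIDMC,VFERTRSLGLV,MLQWG,IPHNVNGC,GCQCVICGMVELK,0,1,shuffled_negative
IDIRINWYIV,LEVSFSA,PLPTWG,QFICSKMHIFYWK,MDICD,KSMNKADT,NSVKRMVGTMFPAE,0,1,shuffled_negative
RGSEMGCEGMI,PELHNPH,PEIDQN,QQLYLLADKRAD,HGRSW,KVTMTMTK,GYFMCYFTSRKPQ,0,1,shuffled_negative
RGSEMGCEGMI,MLGPQY,IKWWGEM,INMANYQDLPLQRF,CWWSILV,SCSEHPHI,SPNKRMDGFPEAH,0,1,shuffled_negative
RGSEMGCEGMI,CDVIP,RVIQCSTT,MREKLHALTWCRDQE,VGYTE,RCDFES,CGYMCYYIHGLTEHV,0,1,shuffled_negative
RGSEMGCEGMI,LEVSFSA,PLPTWG,QFICSKMHIFYWK,MDICD,KSMNKADT,NSVKRMVGTMFPAE,0,1,shuffled_negative
TQEDPKIPRKC,CDVIP,RVIQCSTT,MREKLHALTWCRDQE,VGYTE,RCDFES,CGYMCYYIHGLTEHV,0,1,shuffled_negative
TQEDPKIPRKC,WDDWF,APVWAQ,CLSAWKLDEYNVDD,PTMRF,YIMMSF,TFPKRMLAWYFEI,0,1,shuffled_negative
TQEDPKIPRKC,IFWNC,LMQPGN,PWYSFHTNPSR,GDHENA,CWELAYT,WPICVIKRMMTNDDV,0,1,shuffled_negative
NILQISVFGDK,AMTPV,NDYPIDMC,VFERTRSLGLV,MLQWG,IPHNVNGC,GCQCVICGMVELK,0,1,shuffled_negative
NILQISVFGDK,PELHNPH,PEIDQN,QQLYLLADKRAD,HGRSW,KVTMTMTK,GYFMCYFTSRKPQ,0,1,shuffled_negative
NILQISVFGDK,FYVHY,QKNKDK,SIWWLNIVGHR,AKMMLI,DNYVIDTH,TGIFTSWFKNEQHCEE,0,1,shuffled_negative
NILQISVFGDK,GKFWASI,GLWCNGE,PELDALMDFTKSE,PACSPMH,MDYPSKIE,HKDFTSSYHNCTM,0,1,shuffled_negative
NILQISVFGDK,NQMKIAM,TAWPMGL,AKHETGEFEV,KYHCYY,APGASAC,WACMCYKRDLNTM,0,1,shuffled_negative
TQEDPKIPRKC,RCRMED,DDDCEI,YPPLQPEMMNWPHY,HIAPLF,CPTQTKH,HVMMCYYWDWCRFP,0,1,shuffled_negative
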