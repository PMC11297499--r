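A1,A2,A3,B1,B2,B3
LHTYF,RGKLGKT,VGFFRWFRFNNDCNR,VNDFTHY,HPYDPADL,TNGRRHKNGEYSL
NKFYNY,IEMFDQD,NEVASPLYKHQRDR,QYVWM,YCPSHGG,KWNFPHPCTDFT
RMQHTNR,GGNYIKQ,YMGDHWCKSQF,ACYHLRN,GFFFMRM,ILQDHHYICYHAYFKK
WRMGCCQ,FAFECYWW,WKHGEPDLGNA,RMFHCIF,DHMMRNSS,NFAEPLNWCVWRCRAI
FTASNK,CWNSMYK,TEDFSNNKAE,YNNIN,HTLWCYH,HTGHVMLHEFMVKNT
GNSKFEK,NGRWDM,RDAFIDFTDFC,RQASRT,QMDATV,QEYNSIKMCMLLG
NTCCF,IYLAHY,FKFLGEEGYKINECCA,DKKDTKF,TAVELKD,FQIIDEFCFFIHHN
WLEFF,KDGSHP,RIILQHNKAYKRCFI,INIES,DNIDNWN,FSSRKEFMHQEC
AYYWK,NFPMAFSC,EYCKWTFMHIAQPEFL,QCVKLVW,HRILKGE,NACCPRAEGNFMN
RGVFYP,IHCCLSID,SNHALTFIPLARFWT,AEWFDT,IGRPIR,HIVETVFSWFFK
MGWDQA,MLFKHAA,FKMMETFAMSVFA,LANEF,EYGASE,PPIMLDPDLGHRLLW
QIKYMN,YPKDVA,MKFNFGWFPGIYCINP,VIHPG,LQAHTFP,NNYVHFNKIYRIF
ADNMH,QHKPRNQ,IFARDCGNICTYRTA,TQDKTLR,VGKHFKIF,ACVNCHCQGWKED
WSHYD,GFWENSNV,KNEMEFHTENS,KIEFET,EPMFFTC,FETIGVGIPHSIGYPF
TNAFIA,NCCLGYS,CKGFVENNNMKACP,DGVSC,MPGYTSNY,KNYYIIGGIFCNIIGS
MCQETGK,FQNCMIF,EPTCCDKTYVEEG,MCRSF,CMNDIQN,DDPNSGYFYFLNG
HTTNN,VLIELY,GKCMETPEYKCI,WYNRD,CGFEHC,MFAEGNMIKLSTAFMF
TIIGF,FDFMNWH,FHTINMHQQHGHIF,RKLWPIP,HPNRTW,ELQLPFPCFGTNQEKV
RRGFK,NGNDKTH,QPNELPLHSLQ,RDYDFQE,CGCGVKQI,IRNHTYTTQTHQFP
AFHPN,AGNAGNS,SVFCAMQTRPKKA,TEEKRR,SIDQRSV,IVNTEDITCNHMDVVT
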