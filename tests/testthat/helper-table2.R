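# Published per-drug 2x2 cells and display-rounded statistics for the
# three-database ovarian-cancer / ILD analysis (per-universe panels plus
# the pooled panel). `errata` marks the handful of printed cells that are
# internally inconsistent with the publication's own formulas (e.g. an IC
# whose own printed IC025 back-computes to a different IC); those cells
# are excluded from reproduction checks.
published_signal_rows <- function() {
  tab <- read.csv(text = 'universe,drug,a,b,c,d,prr,prr_lo,prr_hi,ror,ror_lo,ror_hi,chi2,ic,ic025,errata
COMBINED,niraparib tosylate monohydrate,607,3482,147133,228418,0.27,0.25,0.30,0.27,0.25,0.30,1000.53,-1.39,-1.52,chi2
COMBINED,olaparib,768,3321,22977,352574,3.47,3.21,3.74,3.55,3.28,3.84,1106.36,1.58,1.47,
COMBINED,bevacizumab,481,3608,45736,329815,0.96,0.87,1.06,0.96,0.87,1.06,0.65,-0.05,-0.20,
COMBINED,rucaparib camsylate,81,4008,31093,344458,0.23,0.18,0.28,0.22,0.18,0.28,212.89,-2.04,-2.41,
COMBINED,mirvetuximab soravtansine-gynx,33,4056,847,374704,3.50,2.50,4.90,3.60,2.54,5.10,59.15,1.75,1.17,
COMBINED,carboplatin,341,3748,30507,345044,1.03,0.92,1.15,1.03,0.92,1.15,0.25,0.04,-0.14,
COMBINED,cisplatin,90,3999,4400,371151,1.88,1.53,2.31,1.90,1.54,2.34,36.68,0.89,0.54,
COMBINED,cyclophosphamide,34,4055,1852,373699,1.68,1.20,2.35,1.69,1.20,2.38,9.37,0.73,0.16,
COMBINED,gemcitabine hydrochloride,151,3938,5692,369859,2.45,2.09,2.88,2.49,2.11,2.94,126.53,1.26,0.99,
COMBINED,doxorubicin hydrochloride,416,3673,11387,364164,3.53,3.19,3.90,3.62,3.27,4.02,684.85,1.71,1.54,
COMBINED,doxorubicin hydrochloride liposome,16,4073,897,374654,1.63,1.00,2.65,1.64,1.00,2.70,3.92,0.68,-0.17,ror_hi
COMBINED,topotecan hydrochloride,6,4083,1080,374471,0.51,0.23,1.14,0.51,0.23,1.14,2.81,-0.91,-2.32,
COMBINED,paclitaxel,404,3685,33670,341881,1.11,1.00,1.23,1.11,1.00,1.23,4.14,0.14,-0.03,
FAERS,niraparib tosylate monohydrate,513,2270,138129,173990,0.29,0.26,0.32,0.28,0.26,0.31,746.34,-1.26,-1.40,
FAERS,olaparib,495,2288,18529,293590,3.36,3.06,3.70,3.43,3.11,3.78,682.39,1.56,1.41,
FAERS,bevacizumab,318,2465,24624,287495,1.50,1.34,1.68,1.51,1.34,1.69,47.32,0.53,0.34,
FAERS,rucaparib camsylate,81,2702,31093,281026,0.27,0.22,0.34,0.27,0.22,0.34,153.77,-1.76,-2.13,
FAERS,mirvetuximab soravtansine-gynx,33,2750,874,311245,4.15,2.97,5.82,4.27,3.01,6.06,78.79,1.98,1.40,
FAERS,carboplatin,299,2484,28214,283905,1.21,1.07,1.36,1.21,1.07,1.37,9.73,0.25,0.06,
FAERS,cisplatin,52,2731,3983,308136,1.47,1.12,1.93,1.47,1.12,1.94,7.65,0.54,0.08,
FAERS,cyclophosphamide,27,2756,1789,310330,1.70,1.16,2.46,1.70,1.16,2.50,7.58,0.73,0.09,prr;ror_hi
FAERS,gemcitabine hydrochloride,89,2694,5267,306852,1.91,1.55,2.35,1.92,1.56,2.38,37.64,0.90,0.55,
FAERS,doxorubicin hydrochloride,177,2606,7451,304668,2.74,2.35,3.18,2.78,2.38,3.24,184.19,1.39,1.14,
FAERS,topotecan hydrochloride,6,2777,1080,311039,0.62,0.28,1.39,0.62,0.28,1.39,1.37,-0.64,-2.05,
FAERS,paclitaxel,265,2518,23640,288479,1.28,1.13,1.45,1.28,1.13,1.46,14.92,0.33,0.12,
CVAR,niraparib tosylate monohydrate,21,313,5684,37308,0.44,0.28,0.69,0.44,0.28,0.69,13.94,-1.05,-1.78,
CVAR,olaparib,15,319,581,42411,3.37,2.02,5.62,3.43,2.03,5.80,24.08,1.61,0.73,
CVAR,bevacizumab,108,226,19086,23906,0.60,0.48,0.76,0.60,0.48,0.75,19.53,-0.45,-0.77,
CVAR,cyclophosphamide,7,327,63,42929,13.23,6.50,26.93,14.59,6.63,32.09,78.07,2.85,1.55,
CVAR,doxorubicin hydrochloride,20,314,895,42097,2.95,1.89,4.62,3.00,1.90,4.73,24.46,1.44,0.69,
CVAR,paclitaxel,100,234,7976,35016,1.87,1.48,2.35,1.88,1.48,2.37,28.34,0.70,0.35,ic
CVAR,doxorubicin hydrochloride liposome,16,318,897,42095,2.34,1.42,3.85,2.36,1.42,3.92,11.75,1.13,0.29,
JADER,niraparib tosylate monohydrate,73,899,3320,17120,0.43,0.34,0.55,0.42,0.33,0.53,53.06,-1.07,-1.46,
JADER,olaparib,258,714,3867,16573,1.51,1.32,1.74,1.55,1.34,1.79,34.70,0.46,0.26,chi2
JADER,bevacizumab,55,917,2026,18414,0.56,0.43,0.73,0.55,0.41,0.72,19.13,-0.77,-1.22,
JADER,carboplatin,40,932,2295,18145,0.35,0.26,0.48,0.34,0.25,0.47,48.32,-1.39,-1.92,
JADER,cisplatin,38,934,417,20023,1.87,1.37,2.56,1.95,1.39,2.74,15.59,0.86,0.32,
JADER,gemcitabine hydrochloride,62,910,425,20015,2.92,2.30,3.73,3.21,2.44,4.22,77.16,1.47,1.05,prr
JADER,doxorubicin hydrochloride,219,753,3041,17399,1.62,1.40,1.87,1.66,1.42,1.94,42.11,0.56,0.34,
JADER,paclitaxel,39,933,2054,18386,0.39,0.28,0.53,0.37,0.27,0.52,38.34,-1.27,-1.81,',
    check.names = FALSE, stringsAsFactors = FALSE)
  tab$errata[is.na(tab$errata)] <- ""
  tab
}
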