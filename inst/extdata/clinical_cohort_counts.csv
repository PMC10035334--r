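subject_id,algorithm,a_spindle,r_spindle,e_spindle
DS1,morlet,732,647,1136
DS1,rms,1409,998,1136
DS1,hmm_svm,1258,994,1136
DS1,fusion,1124,1005,1136
DS2,morlet,467,424,730
DS2,rms,831,602,730
DS2,hmm_svm,802,685,730
DS2,fusion,725,668,730
DS3,morlet,263,229,551
DS3,rms,518,383,551
DS3,hmm_svm,617,527,551
DS3,fusion,511,472,551
DS4,morlet,231,204,493
DS4,rms,589,406,493
DS4,hmm_svm,523,436,493
DS4,fusion,456,429,493
DS5,morlet,439,376,848
DS5,rms,977,747,848
DS5,hmm_svm,821,765,848
DS5,fusion,792,763,848
DS6,morlet,184,160,590
DS6,rms,632,491,590
DS6,hmm_svm,635,532,590
DS6,fusion,530,487,590
DS7,morlet,702,605,1073
DS7,rms,1346,984,1073
DS7,hmm_svm,866,603,1073
DS7,fusion,1063,994,1073
DS8,morlet,479,427,657
DS8,rms,746,590,657
DS8,hmm_svm,733,616,657
DS8,fusion,630,581,657
DS9,morlet,212,187,706
DS9,rms,692,526,706
DS9,hmm_svm,805,668,706
DS9,fusion,621,578,706
DS10,morlet,643,574,779
DS10,rms,846,669,779
DS10,hmm_svm,762,694,779
DS10,fusion,792,706,779
DS11,morlet,752,629,1265
DS11,rms,1415,1070,1265
DS11,hmm_svm,1238,1035,1265
DS11,fusion,1248,1125,1265
DS12,morlet,525,481,819
DS12,rms,968,708,819
DS12,hmm_svm,774,688,819
DS12,fusion,834,761,819
DS13,morlet,596,528,676
DS13,rms,724,571,676
DS13,hmm_svm,729,605,676
DS13,fusion,634,583,676
DS14,morlet,381,334,798
DS14,rms,898,639,798
DS14,hmm_svm,880,763,798
DS14,fusion,759,702,798
DS15,morlet,1066,938,1491
DS15,rms,1635,1323,1491
DS15,hmm_svm,1458,1237,1491
DS15,fusion,1507,1359,1491
DS16,morlet,539,456,736
DS16,rms,736,608,736
DS16,hmm_svm,664,503,736
DS16,fusion,687,643,736
DS17,morlet,551,492,839
DS17,rms,939,712,839
DS17,hmm_svm,875,756,839
DS17,fusion,835,765,839
DS18,morlet,572,489,763
DS18,rms,929,674,763
DS18,hmm_svm,802,701,763
DS18,fusion,790,688,763
DS19,morlet,360,324,702
DS19,rms,727,598,702
DS19,hmm_svm,768,654,702
DS19,fusion,689,640,702
DS20,morlet,736,635,891
DS20,rms,965,763,891
DS20,hmm_svm,1033,789,891
DS20,fusion,856,784,891
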