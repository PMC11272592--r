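group,domain,object_id,word,cognate_id,unique_to_cahg,confidence
G02,music,music_obj_M01,wM01_G02,M01,TRUE,conclusive
G03,music,music_obj_M01,wM01_G03,M01,TRUE,conclusive
G03,music,music_obj_M02,wM02_G03,M02,TRUE,conclusive
G04,music,music_obj_M02,wM02_G04,M02,TRUE,conclusive
G04,music,music_obj_M03,wM03_G04,M03,TRUE,tentative
G05,music,music_obj_M03,wM03_G05,M03,TRUE,tentative
G05,music,music_obj_M04,wM04_G05,M04,TRUE,conclusive
G06,music,music_obj_M04,wM04_G06,M04,TRUE,conclusive
G06,music,music_obj_M05,wM05_G06,M05,TRUE,conclusive
G07,music,music_obj_M05,wM05_G07,M05,TRUE,conclusive
G07,music,music_obj_M06,wM06_G07,M06,TRUE,tentative
G08,music,music_obj_M06,wM06_G08,M06,TRUE,tentative
G08,music,music_obj_M07,wM07_G08,M07,TRUE,conclusive
G09,music,music_obj_M07,wM07_G09,M07,TRUE,conclusive
G09,music,music_obj_M08,wM08_G09,M08,TRUE,conclusive
G10,music,music_obj_M08,wM08_G10,M08,TRUE,conclusive
G10,music,music_obj_M09,wM09_G10,M09,TRUE,tentative
G01,music,music_obj_M09,wM09_G01,M09,TRUE,tentative
G01,music,music_obj_M10,wM10_G01,M10,TRUE,conclusive
G02,music,music_obj_M10,wM10_G02,M10,TRUE,conclusive
G02,music,music_obj_M11,wM11_G02,M11,TRUE,conclusive
G03,music,music_obj_M11,wM11_G03,M11,TRUE,conclusive
G03,music,music_obj_M12,wM12_G03,M12,FALSE,tentative
G04,music,music_obj_M12,wM12_G04,M12,FALSE,tentative
G04,music,music_obj_M13,wM13_G04,M13,FALSE,conclusive
G05,music,music_obj_M13,wM13_G05,M13,FALSE,conclusive
G05,music,music_obj_M14,wM14_G05,M14,FALSE,conclusive
G06,music,music_obj_M14,wM14_G06,M14,FALSE,conclusive
G06,music,music_obj_M15,wM15_G06,M15,FALSE,tentative
G07,music,music_obj_M15,wM15_G07,M15,FALSE,tentative
G07,music,music_obj_M16,wM16_G07,M16,FALSE,conclusive
G08,music,music_obj_M16,wM16_G08,M16,FALSE,conclusive
G08,music,music_obj_M17,wM17_G08,M17,FALSE,conclusive
G09,music,music_obj_M17,wM17_G09,M17,FALSE,conclusive
G03,music,music_obj_M18,wM18_G03,M18,TRUE,conclusive
G04,music,music_obj_M18,wM18_G04,M18,TRUE,conclusive
G05,music,music_obj_M18,wM18_G05,M18,TRUE,conclusive
G05,music,music_obj_M19,wM19_G05,M19,TRUE,conclusive
G06,music,music_obj_M19,wM19_G06,M19,TRUE,conclusive
G07,music,music_obj_M19,wM19_G07,M19,TRUE,conclusive
G07,music,music_obj_M20,wM20_G07,M20,FALSE,conclusive
G08,music,music_obj_M20,wM20_G08,M20,FALSE,conclusive
G09,music,music_obj_M20,wM20_G09,M20,FALSE,conclusive
G04,music,music_obj_M21,wM21_G04,M21,TRUE,conclusive
G05,music,music_obj_M21,wM21_G05,M21,TRUE,conclusive
G06,music,music_obj_M21,wM21_G06,M21,TRUE,conclusive
G07,music,music_obj_M21,wM21_G07,M21,TRUE,conclusive
G07,music,music_obj_M22,wM22_G07,M22,FALSE,conclusive
G08,music,music_obj_M22,wM22_G08,M22,FALSE,conclusive
G09,music,music_obj_M22,wM22_G09,M22,FALSE,conclusive
G10,music,music_obj_M22,wM22_G10,M22,FALSE,conclusive
G10,music,music_obj_M23,wM23_G10,M23,FALSE,conclusive
G01,music,music_obj_M23,wM23_G01,M23,FALSE,conclusive
G02,music,music_obj_M23,wM23_G02,M23,FALSE,conclusive
G03,music,music_obj_M23,wM23_G03,M23,FALSE,conclusive
G05,music,music_obj_M24,wM24_G05,M24,TRUE,conclusive
G06,music,music_obj_M24,wM24_G06,M24,TRUE,conclusive
G07,music,music_obj_M24,wM24_G07,M24,TRUE,conclusive
G08,music,music_obj_M24,wM24_G08,M24,TRUE,conclusive
G09,music,music_obj_M24,wM24_G09,M24,TRUE,conclusive
G01,music,music_solo_1,solo1,MS1,FALSE,conclusive
G02,music,music_solo_2,solo2,MS2,FALSE,conclusive
G03,music,music_solo_3,solo3,MS3,FALSE,conclusive
G04,music,music_solo_4,solo4,MS4,FALSE,conclusive
G05,music,music_solo_5,solo5,MS5,FALSE,conclusive
G03,subsistence,subsistence_obj_T01,wT01_G03,T01,TRUE,conclusive
G04,subsistence,subsistence_obj_T01,wT01_G04,T01,TRUE,conclusive
G04,subsistence,subsistence_obj_T02,wT02_G04,T02,TRUE,conclusive
G05,subsistence,subsistence_obj_T02,wT02_G05,T02,TRUE,conclusive
G05,subsistence,subsistence_obj_T03,wT03_G05,T03,TRUE,conclusive
G06,subsistence,subsistence_obj_T03,wT03_G06,T03,TRUE,conclusive
G06,subsistence,subsistence_obj_T04,wT04_G06,T04,FALSE,conclusive
G07,subsistence,subsistence_obj_T04,wT04_G07,T04,FALSE,conclusive
G07,subsistence,subsistence_obj_T05,wT05_G07,T05,FALSE,conclusive
G08,subsistence,subsistence_obj_T05,wT05_G08,T05,FALSE,conclusive
G08,subsistence,subsistence_obj_T06,wT06_G08,T06,FALSE,conclusive
G09,subsistence,subsistence_obj_T06,wT06_G09,T06,FALSE,conclusive
G09,subsistence,subsistence_obj_T07,wT07_G09,T07,FALSE,conclusive
G10,subsistence,subsistence_obj_T07,wT07_G10,T07,FALSE,conclusive
G10,subsistence,subsistence_obj_T08,wT08_G10,T08,FALSE,conclusive
G01,subsistence,subsistence_obj_T08,wT08_G01,T08,FALSE,conclusive
G01,subsistence,subsistence_obj_T09,wT09_G01,T09,FALSE,conclusive
G02,subsistence,subsistence_obj_T09,wT09_G02,T09,FALSE,conclusive
G02,subsistence,subsistence_obj_T10,wT10_G02,T10,FALSE,conclusive
G03,subsistence,subsistence_obj_T10,wT10_G03,T10,FALSE,conclusive
G03,subsistence,subsistence_obj_T11,wT11_G03,T11,FALSE,conclusive
G04,subsistence,subsistence_obj_T11,wT11_G04,T11,FALSE,conclusive
G05,subsistence,subsistence_obj_T11,wT11_G05,T11,FALSE,conclusive
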