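SubjectID,ExamDate,Diagnosis
SUBJ0001,2010-01-01,NC
SUBJ0002,2010-01-02,NC
SUBJ0003,2010-01-03,NC
SUBJ0004,2010-01-04,NC
SUBJ0005,2010-01-05,NC
SUBJ0006,2010-01-06,NC
SUBJ0007,2010-01-07,NC
SUBJ0008,2010-01-08,NC
SUBJ0009,2010-01-09,NC
SUBJ0010,2010-01-10,NC
SUBJ0011,2010-01-11,NC
SUBJ0012,2010-01-12,NC
SUBJ0013,2010-01-13,NC
SUBJ0014,2010-01-14,NC
SUBJ0015,2010-01-15,NC
SUBJ0016,2010-01-16,MCI
SUBJ0017,2010-01-17,MCI
SUBJ0018,2010-01-18,MCI
SUBJ0019,2010-01-19,MCI
SUBJ0020,2010-01-20,MCI
SUBJ0021,2010-01-21,MCI
SUBJ0022,2010-01-22,MCI
SUBJ0023,2010-01-23,MCI
SUBJ0024,2010-01-24,MCI
SUBJ0025,2010-01-25,MCI
SUBJ0026,2010-01-26,MCI
SUBJ0027,2010-01-27,MCI
SUBJ0028,2010-01-28,MCI
SUBJ0029,2010-01-29,MCI
SUBJ0030,2010-01-30,MCI
SUBJ0031,2010-01-31,AD
SUBJ0032,2010-02-01,AD
SUBJ0033,2010-02-02,AD
SUBJ0034,2010-02-03,AD
SUBJ0035,2010-02-04,AD
SUBJ0036,2010-02-05,AD
SUBJ0037,2010-02-06,AD
SUBJ0038,2010-02-07,AD
SUBJ0039,2010-02-08,AD
SUBJ0040,2010-02-09,AD
SUBJ0041,2010-02-10,AD
SUBJ0042,2010-02-11,AD
SUBJ0043,2010-02-12,AD
SUBJ0044,2010-02-13,AD
SUBJ0045,2010-02-14,AD
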