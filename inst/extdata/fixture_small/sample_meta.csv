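SampleID,SubjectID,CollectionDate
SUBJ0001,SUBJ0001,2010-01-01
SUBJ0002,SUBJ0002,2010-01-02
SUBJ0003,SUBJ0003,2010-01-03
SUBJ0004,SUBJ0004,2010-01-04
SUBJ0005,SUBJ0005,2010-01-05
SUBJ0006,SUBJ0006,2010-01-06
SUBJ0007,SUBJ0007,2010-01-07
SUBJ0008,SUBJ0008,2010-01-08
SUBJ0009,SUBJ0009,2010-01-09
SUBJ0010,SUBJ0010,2010-01-10
SUBJ0011,SUBJ0011,2010-01-11
SUBJ0012,SUBJ0012,2010-01-12
SUBJ0013,SUBJ0013,2010-01-13
SUBJ0014,SUBJ0014,2010-01-14
SUBJ0015,SUBJ0015,2010-01-15
SUBJ0016,SUBJ0016,2010-01-16
SUBJ0017,SUBJ0017,2010-01-17
SUBJ0018,SUBJ0018,2010-01-18
SUBJ0019,SUBJ0019,2010-01-19
SUBJ0020,SUBJ0020,2010-01-20
SUBJ0021,SUBJ0021,2010-01-21
SUBJ0022,SUBJ0022,2010-01-22
SUBJ0023,SUBJ0023,2010-01-23
SUBJ0024,SUBJ0024,2010-01-24
SUBJ0025,SUBJ0025,2010-01-25
SUBJ0026,SUBJ0026,2010-01-26
SUBJ0027,SUBJ0027,2010-01-27
SUBJ0028,SUBJ0028,2010-01-28
SUBJ0029,SUBJ0029,2010-01-29
SUBJ0030,SUBJ0030,2010-01-30
SUBJ0031,SUBJ0031,2010-01-31
SUBJ0032,SUBJ0032,2010-02-01
SUBJ0033,SUBJ0033,2010-02-02
SUBJ0034,SUBJ0034,2010-02-03
SUBJ0035,SUBJ0035,2010-02-04
SUBJ0036,SUBJ0036,2010-02-05
SUBJ0037,SUBJ0037,2010-02-06
SUBJ0038,SUBJ0038,2010-02-07
SUBJ0039,SUBJ0039,2010-02-08
SUBJ0040,SUBJ0040,2010-02-09
SUBJ0041,SUBJ0041,2010-02-10
SUBJ0042,SUBJ0042,2010-02-11
SUBJ0043,SUBJ0043,2010-02-12
SUBJ0044,SUBJ0044,2010-02-13
SUBJ0045,SUBJ0045,2010-02-14
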