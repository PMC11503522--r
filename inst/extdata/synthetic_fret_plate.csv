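well,role,i_donor_ch,i_acceptor_ch,i_fret_ch,detergent,cmc_multiple
A1,sample,997.4941847570307,801.3180310872615,587.303125406614,OGNG,2
A2,donor_only,1000.7345732968884,-3.281873536472061,98.77844645137458,OGNG,2
A3,acceptor_only,-3.3425144496401886,801.949716209714,206.04712467380338,OGNG,2
A4,blank,6.381123208551166,2.9532988205168693,1.5593729456457244,OGNG,2
A1,sample,996.4123418135001,799.6789929737961,442.93789574661173,OGNG,10
A2,donor_only,1000.739396738587,0.5296811375243778,99.44485195152134,OGNG,10
A3,acceptor_only,6.351381324835293,802.8318189170869,201.67060300317021,OGNG,10
A4,blank,-4.5215026969851415,-0.9587920966873604,3.927011109854647,OGNG,10
A1,sample,996.1522663363205,800.7831313051455,385.12457033768806,C8E4,2
A2,donor_only,998.8298971084861,0.12049577840652612,105.06947488835955,C8E4,2
A3,acceptor_only,1.035152864965006,800.3416709264491,197.02087361545944,C8E4,2
A4,blank,-4.60852754366053,4.466440850861063,-4.524874283342944,C8E4,2
A1,sample,1000.8670194514543,806.5424720044518,337.5861594876371,C8E4,10
A2,donor_only,997.8300297109463,2.7571017676788907,107.1074528547309,C8E4,10
A3,acceptor_only,3.56457858028931,794.8750134795954,202.26641799272127,C8E4,10
A4,blank,2.3839223087498986,-0.8525780771134505,0.06287781601828006,C8E4,10
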