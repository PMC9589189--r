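gene,haplotype_label,variant_sites,accession_or_rsid,maf_pct,freq_pct,functional
OR10A6,ref,,NM_001004461.2,,21.81,FALSE
OR10A6,V140G,rs79338074,rs79338074,1.3,,FALSE
OR10A6,A117V,rs79284513,rs79284513,9.4,0.08,FALSE
OR10A6,L287P,rs4758258,rs4758258,21.2,35.02,TRUE
OR10A6,A117V/V140G/L287P,rs79284513;rs79338074;rs4758258,,,37.33,FALSE
OR10A6,V140G/L287P,rs79338074;rs4758258,,,1.92,FALSE
OR10A6,A117V/L287P,rs79284513;rs4758258,,,0.15,FALSE
OR2W1,ref,,NM_030903.3,,72.43,TRUE
OR2W1,M81V,rs34892006,rs34892006,3.9,3.61,FALSE
OR2W1,D296N,rs35771565,rs35771565,24.9,23.96,TRUE
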