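"equation_id","citation_label","modality","output_kind","age_min","age_max","required_inputs","height_unit","external_only","formula"
"durnin_womersley_1974","Durnin and Womersley, 1974","anthropometry","body_density",16,68,"TR;BC;SE;SI",,FALSE,"BD = 1.1567 - 0.0717*log10(TR+BC+SE+SI)"
"jackson_pollock_1980","Jackson and Pollock, 1980","anthropometry","body_density",18,55,"TR;TH;SI;A",,FALSE,"BD = 1.0994921 - 0.0009929*S + 0.0000023*S^2 - 0.0001392*A; S = TR+TH+SI"
"guedes_1985","Guedes, 1985","anthropometry","body_density",17,27,"TH;SI;SE",,FALSE,"BD = 1.1665 - 0.0706*log10(TH+SI+SE)"
"petroski_1995","Petroski and Pires-Neto, 1995","anthropometry","body_density",18,51,"AX;SI;TH;CA;A",,FALSE,"BD = 1.19547130 - 0.07513507*log10(AX+SI+TH+CA) - 0.00041072*A"
"sloan_1962","Sloan, 1962","anthropometry","body_density",17,25,"SI;TR",,FALSE,"BD = 1.0764 - 0.00081*SI - 0.00088*TR"
"hergenroeder_1993","Hergenroeder, et al., 1993","anthropometry","ffm_kg",11,25,"W",,FALSE,"FFM = 0.73*W + 3.0"
"jackson_pollock_1975","Jackson and Pollock, 1975","anthropometry","body_density",18,29,"TR;SI;TH;AB;A",,FALSE,"BD = 1.096095 - 0.0006952*S + 0.0000011*S^2 - 0.0000714*A; S = TR+SI+TH+AB"
"slaughter_1988","Slaughter et al., 1988","anthropometry","bf_percent",7,18,"TR;SE",,FALSE,"BF% = 1.33*(TR+SE) - 0.013*(TR+SE)^2 - 2.5"
"rjl_manufacturer","Manufacturer Equation - RJL Systems","bia","ffm_kg",,,"W",,TRUE,"undisclosed; supply predictions via external_pred"
"chumlea_2002","Chumlea, et al., 2002","bia","ffm_kg",12,80,"W;H;R","cm",FALSE,"FFM = -9.529 + 0.168*W + 0.696*H^2/R + 0.016*R"
"segal_1988","Segal, et al., 1988","bia","ffm_kg",17,62,"W;H;R","cm",FALSE,"FFM = 5.091 + 0.6483*H^2/R + 0.1699*W"
"gray_1989","Gray, et al., 1989","bia","ffm_kg",19,74,"H;R;W;A","cm",FALSE,"FFM = 0.00151*H^2 - 0.0344*R + 0.140*W - 0.158*A + 20.387"
"lukaski_1986","Lukaski, et al., 1986","bia","ffm_kg",19,50,"H;R;W;Xc","cm",FALSE,"FFM = 0.756*H^2/R + 0.110*W + 0.107*Xc - 5.463"
"deurenberg_child_1991","Deurenberg, et al., 1991 (7-15 y)","bia","ffm_kg",7,15,"H;R;W;sex","m",FALSE,"FFM = 0.406*(1e4*H^2/R) + 0.360*W + 5.58*H + 0.56*sex - 6.48"
"deurenberg_adult_1991","Deurenberg, et al., 1991 (16-83 y)","bia","ffm_kg",16,83,"H;R;W;A;sex","m",FALSE,"FFM = 0.340*(1e4*H^2/R) + 15.34*H + 0.273*W - 0.127*A + 4.56*sex - 12.44"
"houtkooper_1992","Houtkooper, et al., 1992","bia","ffm_kg",10,19,"H;R;W","cm",FALSE,"FFM = 0.61*H^2/R + 0.25*W + 1.31"
"kyle_2001","Kyle, et al., 2001","bia","ffm_kg",20,94,"H;R;W;Xc;sex","cm",FALSE,"FFM = -4.104 + 0.518*H^2/R + 0.231*W + 0.130*Xc + 4.229*sex"
"sun_2003","Sun, et al., 2003","bia","ffm_kg",12,94,"H;R;W","cm",FALSE,"FFM = -9.53 + 0.69*H^2/R + 0.17*W + 0.02*R"
"yannakoulia_a_2000","Yannakoulia, et al., 2000 (BIA only)","bia","ffm_kg",18,26,"W;H;R","cm",FALSE,"FFM = 0.247*W + 0.214*H^2/R + 0.191*H - 14.96"
"yannakoulia_b_2000","Yannakoulia, et al., 2000 (BIA + triceps)","bia","ffm_kg",18,26,"W;H;R;TR","cm",FALSE,"FFM = 0.391*W + 0.168*H - 0.253*TR + 0.144*H^2/R - 9.49"
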