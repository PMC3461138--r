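synthetic two-epoch example (Kerr site, 9 loci; generated by makePaperStudy, seed 42)
L1
L2
L3
L4
L5
L6
L7
L8
L9
POP
Kerr_1915_01 , 024030 019016 021020 021021 021024 021016 016016 025023 018018
Kerr_1915_02 , 020030 018020 020020 021020 019021 015016 026014 021021 020022
Kerr_1915_03 , 021022 018016 022020 022020 019021 016019 020018 021025 018019
Kerr_1915_04 , 020023 018018 022022 022019 024024 018016 015013 024024 019019
Kerr_1915_05 , 017029 020018 022019 020020 021018 016016 018019 022025 019019
Kerr_1915_06 , 022024 017016 021016 021021 024024 021022 014017 024024 022019
Kerr_1915_07 , 024020 020016 020019 021020 024024 021016 014018 025022 020019
Kerr_1915_08 , 023019 018016 020021 020019 021021 016018 027021 022025 019019
Kerr_1915_09 , 022023 018020 023019 021021 024020 013015 014014 025021 019019
Kerr_1915_10 , 018023 020020 019020 021021 021020 018016 017015 027025 019019
POP
Kerr_2005_01 , 031023 016018 020018 022019 021021 021021 018015 021021 019019
Kerr_2005_02 , 024017 020018 020020 021021 021022 016021 014018 021020 018019
Kerr_2005_03 , 023024 016018 020019 020022 024021 016018 018018 020025 019018
Kerr_2005_04 , 017017 016017 016022 021022 021022 021016 017026 024021 019019
Kerr_2005_05 , 023024 018016 020020 021020 021021 016021 026016 021020 018019
Kerr_2005_06 , 030031 016018 018018 022020 019021 021022 017016 020022 019019
Kerr_2005_07 , 024023 018016 016020 019022 019024 016021 026015 021025 019018
Kerr_2005_08 , 023024 016016 019016 021020 019021 016022 018013 022024 019019
Kerr_2005_09 , 024017 018018 021020 019022 024021 016016 016026 025023 019019
Kerr_2005_10 , 020024 018016 021020 021020 024021 016016 026014 022025 019019
POP
Kerr_2008_01 , 023024 016016 020019 022020 021021 016016 017022 023024 018019
Kerr_2008_02 , 024023 020017 020019 020019 020024 016016 018022 021025 019019
Kerr_2008_03 , 023023 018020 016019 020021 023021 016016 017021 020025 018018
Kerr_2008_04 , 024023 018018 020016 022022 021021 021021 017015 023021 019019
Kerr_2008_05 , 023023 016020 020019 021022 024021 022016 015015 020023 018019
Kerr_2008_06 , 024023 016018 020020 021021 021020 016016 017013 023022 019019
Kerr_2008_07 , 023023 020016 019020 019020 021021 021021 017018 023021 018019
Kerr_2008_08 , 023023 020018 020016 022021 024022 018016 026021 023023 019019
Kerr_2008_09 , 024017 016018 019019 021021 024024 021016 018014 025025 018019
Kerr_2008_10 , 031023 016018 018019 022019 019021 016021 018017 025021 018018
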