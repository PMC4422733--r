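>MAPEG_seed_0
SGPAKRQIKFDTNGTAPKMEAFWNCEWYRSTWFQSQPLPQCMMNFKVKKEHYIVEQKQIYVERVRRAHLN
DAENIAGEITLVGSYQYGKSTFHILRMWFVDRHCFPMNYTMRVCDEISEQHQYEEFLMNDTHCEYWLHSR
KMIM
>MAPEG_seed_1
SWRTFTQRYMKTNGTAPKMETPERCEWQETTFFQSCPLIQCSMDFAVRKQYHIVEHTQIFVERVRRAHLN
DTENITQEIEIKGSYIGMKATFNMLRMYFVHQHCWPVEYGAHLHDEISNNHVYINVLMHHTHCEWWILSR
RLIM
>MAPEG_seed_2
SYQAKHQSRWNANGWSPKMEANWNCWWYRSTWYHSQPGPKKIMMWNIHKEQFLVEHEQFYVERVRRAHLN
DHENIRDQITLLGSYNYRHTTMHILHMPYLDRHCHDEDYTKHVDDCISCKHQEQEFLFQWTKCEYYIKSH
QMVM
>MAPEG_seed_3
SGPWKRQYQFCNNGTAIYMDSIPQCNEFRSTHFQTDPAYQWMMQFKVNKNKWMVEWNHIHVERVRRAHLN
DAENISGSIALFQTYGYSKATFNMLKMFFVDRHKFTIVYSMRVCDNIAEHHQFEEALFQERHCWYWQDSQ
VTIV
>MAPEG_seed_4
SGPTKFQEKIDGNATEFPMEILWNCEDYNVTYFQEQPLRQRMMSITMKKQKYLDEQKNIEVERVRRAHLN
DAENIPAEINFLRTYQARHSTFQMMEMYWVNKHERMADYRIRLNDEISEQHDHENFLVNITHCEFTLYSQ
NMIM
>MAPEG_seed_5
SEYSKKQMKFQTNGAAPQMRTSWQCKFYQSTWIQSQPVPRCFMNFNMDKDHYCVEKMQVHVERVRRAHLN
DRENIAYQIHHMGTYKYQRSTVVMLRMFLHDRHDWTVNYSPTVCDEITEQHQFKKPLKNPSHCEKWMKSR
KIFV
>MAPEG_seed_6
SGNAKRQRKWCTNGRAFNMTAFMECHWEHSTYFQSDPLEQCLMNFMVQKNQYVMEQKDFYVERVRRAHLN
DPENIAEMISLKLSYHQGQATAHIMQMWWVHHHGLPLEYALRRTDFITEQHQPETMLLNVFQCNNFLHSR
TVHQ
>MAPEG_seed_7
SYCSKHQIRFNTNGTTPEMQTINQCEWWNSTWFQHQPLPECVMNVKVHKKEFIVETEQQQVERVRRAHLN
DAENIHTEITCVSYYQFWTTTLFLVRMWMVDRHCMKMNYSFKFKDEIVERHDFKKMLMNNSYCEHMMNSQ
EMFM
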