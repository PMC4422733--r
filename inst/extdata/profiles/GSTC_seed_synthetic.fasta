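>GSTC_seed_0
IYRPSVGIEDSRHIVVLPKGTDRFTWVFGSQDDTHEVELQFNPDEWVDTGIPGLHIGPADVPQTSFGRGR
AKFSCNEKGSCFCVDTKSNSCTTNMKYTKA
>GSTC_seed_1
IFQPTTGQYDSEHISCAPKGTPVMTWMMAAQQNTHKVQLKFSPDEWVETKVGGVHIMPTDVPRTSFGHMR
TIFDKHEKGSNFCKDPKSNSCSTIKNYCKA
>GSTC_seed_2
IFPPDVGMRDAHHIWLLPKGTDKFTVGWRSQDRTSEVELHHNPDERCTTGFPMEHFGPAEVRQAVLGRGR
SKFSWHDNGTCFCPDTRANSCSTQFGYKEF
>GSTC_seed_3
IFRQSVGVKDSQHIVVIHKGADNFTWVYGSQKNAYQVSLVLPPEEWMDTEIRGLHFVFADVPNTCFGQMR
AGFSSNNMGTKFWWDSLSNSCMYQLYYTHA
>GSTC_seed_4
IYRQSVGFHDCNHAVVVPKGARRWTLLYQAQNDAHDVELQWHPDEYMDTTLPAMHIHEADVQATSSGRAQ
AHFSDYKKGTCFCMDTQTNICGTNVKYTHT
>GSTC_seed_5
IYREFLGVQDAQHFMVLPKNTDGFTWVFGWQNDAHYVQLRSHPDESPDTGKPGFHVVPTQVPQSSFGGGT
TKFAPNFKGALVCVDMQTKNCTTKSRYAKA
>GSTC_seed_6
IWQPSVGKKNSEHVIIVMKGTKRFTLDFLTQQQTFEVELRFNPAEWVDTYIPKMHFGEYRVPWTSQGRTR
ASFSSHEDGAWIDMDAKSNACASFMKYTDA
>GSTC_seed_7
IERYSKGIEDAQHFEMFPKFTSKGTWLFGTQDDTGEVELKFHPDEVVETNFPGMHVQPQNVPQSSYGKGR
TKFSDHQIGVNWCMDSHSKSCSTWMKYPKI
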