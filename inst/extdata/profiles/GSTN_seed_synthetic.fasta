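>GSTN_seed_0
PQHAHNYWENNQHFMQHCWHWFGQYEPAGLGFFDTFDEYTATDYSNVKHMEQPRWELVTEQNTWITPATV
IECCDQMQDN
>GSTN_seed_1
PQHAHNYIEEDQHIDWIVWSWFYQYPEAGLGFPTRIDKYTFADFAKVKHRCHMQWRLVTEQNAWMTPNQV
IKCQRKNQDN
>GSTN_seed_2
PQQAANYWNNWDHMMNHWWKWFGKYEPFAMGSFNAFDQYTFQDYNNMMHLEELRWEFVTQQVTKHTPSSH
ILCCDQSVDE
>GSTN_seed_3
PNQAEVYWDNNQHLMQKAWHMFANYEQAGLGYWKTFDNYTTSDRAQLCHFQHPRWELASEQDFWIFPAAS
NECQDQWLDN
>GSTN_seed_4
PEHAHVYFEDMQHMSDHCWHFFHNYEYANLGFYDTFDIYSSADHSNFNHYEHIRWDVMTNQHTWLSPGTV
IHCYNQSQDW
>GSTN_seed_5
PDQSHHYFEYTHHFMHHAWHWFQIYQPAEFGFYQRFDEYWASDYSEMKHYDEFMWDLITEQNLWLTPAGM
IDCCNQLHDN
>GSTN_seed_6
PFRTKNYFEDNQHFVGRAWQWFDQYEPSAMGFIQCWDEVASKDFSQHKHITDPQWELVTEQNTWDSPATK
IECCVNWRDN
>GSTN_seed_7
PNHSIHYWQNENHFMQKCWHWRFEYQGTGVGQFQRFDELSATDINDLKHDNHPHWYLQTEQQTFITPFTV
FECLDQSKDN
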