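>THX_seed_0
HFFIIANEHPDWFPVERAIYPTDVSLRCSACDRRESSRGHGWYCNWLVKDYQYEVNFLGKPERDRCYYDS
DYPNENWVEK
>THX_seed_1
HFFIITNERPQWFKLEHAIFFTQVSLKCSTCGRGESSRIKGTYCCYWVKEWHYEVNYVVRPKQDHSYYKS
EYPNYQFMEH
>THX_seed_2
HQAIISNVHFDYFPVEQAIIRTALSLACSSCDFWEFSRGKGWYGHMLFKNWEYKVHNMGKPECEQCYRQS
EYPKERWIEK
>THX_seed_3
HQNIQTNQSYRMFPLEQSIYRSALSDECEACIRRESSRKHQWYNNWLMKDHEFEVDFLAVPERHKCYYAA
DYPNEKYIEK
>THX_seed_4
HHLGMANEYNKYFEVERSIYHAWMSLECAHCDQRASSLGRAWYGEQLVKDHQYEVSFFHNPEQDRCYYDN
EFPNEQFVES
>THX_seed_5
HFFIVANEIPDRFIWEGAICPTERSLVGHRCEKRGISNWHGWYCKFMFKQCQYDVHFLGIPIRDMCYWNH
KLPNEQWCEK
>THX_seed_6
HFLFIANEYQDYFTKKRSIYPTNVSLREWSCDRNEASLGHVWYIDYAIKQHWFEVNLLCKPKNTRCYQDT
DHPWENYMEK
>THX_seed_7
HHTILSNNYPDWFPVESKIYISDISIRCASCDRRVSSNGYMWYCNWPYKNHQQDVEFMCKPEHGRAYFLT
DWPNNNFVEQ
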