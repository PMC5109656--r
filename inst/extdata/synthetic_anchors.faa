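>flaA2
MNEVTMEHYLQWLTTHRKNYKFAHNWTCNNFKWWVCWTQQYTDFWGDTALCYPDNSIRCAQDCHNPICQSMLYDDINMRM
NMERYTTESKRWHSQDLCSWPTTCRVKPYGDTVDVHYYFSQPFWTYCCGQEWLFHEAFHKYHNVICHALNESQIWLQNCI
QCGLYVCTFPNPSGCRKFNNYPYGPQCPQMHMLKIKCSCVLDHDDPLDIWPCRRHMNHLGWGYDVPNVAKPGFVCPWAWS
HCWSLMGWMTLLWQYVGTLVCKSPSYAMRTYPHAVIKYGGDRTNYLKYPFKWPPCFPHCWWVMKNNACKSVNCPHWVLHM
MWRSQAIQLIAYDFDDSDLKMGYWKAPMWNFFTVTGRKAMASWQEYVHCSCIWRWYIKHYHCTPIDKHNYTVIYIWSHGE
>flaG
MAIDDFGANQKMDEPNWPFYYKSMSHWGEKSILDITQITTFRTTHNQTSEYELEQVQHAHYHDTAFGPSGCCKINCHTEV
MQVVWEPVKRPAYFDQVHMHNRDDNTNQCIFLGVPGIEQR
>comFA
MIIMRSLCMLTPYTRHGWQLMISECNWYGGHTIMNGIGRTIERPEISCDNQMPQHCMIGDQCPAVEMVHHPGCWLYWCEN
SKRCSHVISPHDQCDFKAAKFHRPVFFWTSSMKCNGQCADLQVIFTKTRPVPKVLQYDIGTWAVKQEDYRNVDPDYHADH
NMNHHNVGHKGVHAPHRDNHETAEENNEDKRRMPAHHQKHEENGNGAGAASWDCYKLRIPAMNNLIVARHCCPHEWWSAC
MYWGHDNIGTMTFGARIAANLAGLTKFFNTFSVFCNGVKNDGNAQALGMSNCLRNDKMSSSIPFHKTQGNPLNPSGWMKR
YTCTEMMNMRCIQYRGALWEKGCVVLINLGICCDWNGDYCGMNPLPWMNSEFMGAKWKFWEWWRFPNCFWHHHKFWEYGH
MLVQMMMAVFIGISPAKVPTANHVLVTQQPDFEMNYLMGYGCCTALGIWY
>raiA
MLSEYLKIPHTWANGLPMTTSHWSDLPTDVMGIYRADWVTDEFYYNQCHIHSKGWVAKWDENTHIRDPARFMKGIWEVVQ
YESCDYATHWSYEETIKKSYYTMHDQRVLAPMMELALNGKYLCAWYADNLRGVHPRFQKNPWDCNCKWMTVYLSKKNQVI
VSGSWMQPAPTKFSQGKQTL
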