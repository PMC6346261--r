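# name: impaired glucose metabolism (synthetic SMQ stand-in)
# smq_id: 20000041
hyperglycaemia
blood glucose increased
diabetes mellitus
glucose tolerance impaired
glycosylated haemoglobin increased
type 2 diabetes mellitus
type 1 diabetes mellitus
diabetic ketoacidosis
hyperglycaemic hyperosmolar nonketotic syndrome
glycosuria
insulin resistance
impaired fasting glucose
diabetes mellitus inadequate control
blood insulin decreased
gestational diabetes
ketoacidosis
ketonuria
polydipsia
urine ketone body present
blood glucose fluctuation
glucose metabolism disorder (synthetic pt 001)
glucose metabolism disorder (synthetic pt 002)
glucose metabolism disorder (synthetic pt 003)
glucose metabolism disorder (synthetic pt 004)
glucose metabolism disorder (synthetic pt 005)
glucose metabolism disorder (synthetic pt 006)
glucose metabolism disorder (synthetic pt 007)
glucose metabolism disorder (synthetic pt 008)
glucose metabolism disorder (synthetic pt 009)
glucose metabolism disorder (synthetic pt 010)
glucose metabolism disorder (synthetic pt 011)
glucose metabolism disorder (synthetic pt 012)
glucose metabolism disorder (synthetic pt 013)
glucose metabolism disorder (synthetic pt 014)
glucose metabolism disorder (synthetic pt 015)
glucose metabolism disorder (synthetic pt 016)
glucose metabolism disorder (synthetic pt 017)
glucose metabolism disorder (synthetic pt 018)
glucose metabolism disorder (synthetic pt 019)
glucose metabolism disorder (synthetic pt 020)
glucose metabolism disorder (synthetic pt 021)
glucose metabolism disorder (synthetic pt 022)
glucose metabolism disorder (synthetic pt 023)
glucose metabolism disorder (synthetic pt 024)
glucose metabolism disorder (synthetic pt 025)
glucose metabolism disorder (synthetic pt 026)
glucose metabolism disorder (synthetic pt 027)
glucose metabolism disorder (synthetic pt 028)
glucose metabolism disorder (synthetic pt 029)
glucose metabolism disorder (synthetic pt 030)
glucose metabolism disorder (synthetic pt 031)
glucose metabolism disorder (synthetic pt 032)
glucose metabolism disorder (synthetic pt 033)
glucose metabolism disorder (synthetic pt 034)
glucose metabolism disorder (synthetic pt 035)
glucose metabolism disorder (synthetic pt 036)
glucose metabolism disorder (synthetic pt 037)
glucose metabolism disorder (synthetic pt 038)
glucose metabolism disorder (synthetic pt 039)
glucose metabolism disorder (synthetic pt 040)
glucose metabolism disorder (synthetic pt 041)
glucose metabolism disorder (synthetic pt 042)
glucose metabolism disorder (synthetic pt 043)
glucose metabolism disorder (synthetic pt 044)
glucose metabolism disorder (synthetic pt 045)
glucose metabolism disorder (synthetic pt 046)
glucose metabolism disorder (synthetic pt 047)
glucose metabolism disorder (synthetic pt 048)
glucose metabolism disorder (synthetic pt 049)
glucose metabolism disorder (synthetic pt 050)
glucose metabolism disorder (synthetic pt 051)
glucose metabolism disorder (synthetic pt 052)
glucose metabolism disorder (synthetic pt 053)
glucose metabolism disorder (synthetic pt 054)
glucose metabolism disorder (synthetic pt 055)
glucose metabolism disorder (synthetic pt 056)
glucose metabolism disorder (synthetic pt 057)
glucose metabolism disorder (synthetic pt 058)
glucose metabolism disorder (synthetic pt 059)
glucose metabolism disorder (synthetic pt 060)
glucose metabolism disorder (synthetic pt 061)
glucose metabolism disorder (synthetic pt 062)
glucose metabolism disorder (synthetic pt 063)
glucose metabolism disorder (synthetic pt 064)
glucose metabolism disorder (synthetic pt 065)
glucose metabolism disorder (synthetic pt 066)
glucose metabolism disorder (synthetic pt 067)
glucose metabolism disorder (synthetic pt 068)
glucose metabolism disorder (synthetic pt 069)
glucose metabolism disorder (synthetic pt 070)
glucose metabolism disorder (synthetic pt 071)
glucose metabolism disorder (synthetic pt 072)
glucose metabolism disorder (synthetic pt 073)
glucose metabolism disorder (synthetic pt 074)
glucose metabolism disorder (synthetic pt 075)
glucose metabolism disorder (synthetic pt 076)
glucose metabolism disorder (synthetic pt 077)
glucose metabolism disorder (synthetic pt 078)
glucose metabolism disorder (synthetic pt 079)
glucose metabolism disorder (synthetic pt 080)
glucose metabolism disorder (synthetic pt 081)
glucose metabolism disorder (synthetic pt 082)
glucose metabolism disorder (synthetic pt 083)
glucose metabolism disorder (synthetic pt 084)
glucose metabolism disorder (synthetic pt 085)
glucose metabolism disorder (synthetic pt 086)
glucose metabolism disorder (synthetic pt 087)
glucose metabolism disorder (synthetic pt 088)
glucose metabolism disorder (synthetic pt 089)
glucose metabolism disorder (synthetic pt 090)
glucose metabolism disorder (synthetic pt 091)
glucose metabolism disorder (synthetic pt 092)
glucose metabolism disorder (synthetic pt 093)
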