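cdr_trend:
  year:
  - 2000.0
  - 2005.0
  - 2010.0
  - 2015.0
  - 2020.0
  - 2025.0
  - 2030.0
  cdr:
  - 11.509
  - 11.509
  - 11.509
  - 11.509
  - 11.509
  - 11.509
  - 11.509
u5mr_estimate:
  year: 2015
  value: 0.020963238184142
broad_group_envelope:
  group1: 0.110261534451299
  group2: 0.822834303588496
  group3: 0.066904161960205
reference_cause_list:
- A00
- A01
- A02
- A03
- A04
- A05
- A06
- A07
- A08
- A09
- A10
- A11
- A12
- A13
- A14
- A15
- A16
- A17
- A18
- A19
- A20
- A21
- A22
- A23
- A24
- A25
- A26
- A27
- A28
- A29
- A30
- A31
- A32
- A33
- A34
- A35
- A36
- A37
- A38
- A39
- A42
- A43
- A44
- A45
- A46
- A47
- A48
- A49
- A50
- A51
- A52
- A53
- C00
- C01
- C02
- C03
- C04
- C05
- C06
- C07
- C08
- C09
- C10
- C11
- C12
- C13
- C14
- C15
- C16
- C17
- C18
- C19
- C20
- C21
- C22
- C23
- C24
- C25
- C26
- C27
- C28
- C29
- C30
- C31
- C32
- C33
- C34
- C35
- C36
- C37
- C38
- C39
- C40
- C41
- C42
- C43
- C44
- C45
- C46
- C53
- C56
- C61
- D00
- D01
- D02
- D03
- D04
- D05
- D06
- D07
- D08
- D09
- E10
- E11
- E12
- E13
- E14
- F01
- F02
- F03
- F04
- F05
- F06
- F07
- F08
- F09
- G20
- G21
- G22
- G23
- G24
- G25
- G26
- G27
- G28
- G29
- I20
- I21
- I22
- I23
- I24
- I25
- J12
- J13
- J14
- J15
- K25
- K26
- K27
- K28
- K29
- N18
- O10
- O11
- O12
- O13
- P10
- P11
- P12
- P13
- V01
- V02
- V03
- V04
- V05
- V06
- V07
- V08
- V09
- W00
- W01
- W02
- W03
- W04
- W05
- W06
- W07
- W08
- W09
- X00
- X01
- X02
- X03
- X04
- X05
- X06
- X07
- X08
- X09
- Y85
- Y86
- Y87
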