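# Default effluent reuse standards per scenario.
# bound: upper  -> value must be <= high
# bound: lower  -> value must be >= low
# bound: range  -> low <= value <= high
# bound: absent -> target is complete absence (microbiological)
scenarios:
  S1:
    description: "Existing scenario: reuse for restricted irrigation (RI)"
    objectives:
      TDS:   {bound: upper, high: 2500}
      TSS:   {bound: upper, high: 40}
      pH:    {bound: range, low: 6, high: 8.4}
      BOD5:  {bound: upper, high: 40}
      COD:   {bound: upper, high: 50}
      NH3-N: {bound: upper, high: 5}
      NO3-N: {bound: upper, high: 10}
      PO4-P: {bound: upper, high: 10}
      Cl2:   {bound: range, low: 0.2, high: 0.5}
      TC:    {bound: upper, high: 1000}
      FC:    {bound: upper, high: 1000}
  S2:
    description: "Existing scenario: reuse for unrestricted irrigation (URI)"
    objectives:
      TDS:   {bound: upper, high: 2000}
      TSS:   {bound: upper, high: 10}
      pH:    {bound: range, low: 6, high: 8.4}
      BOD5:  {bound: upper, high: 10}
      COD:   {bound: upper, high: 50}
      NH3-N: {bound: upper, high: 5}
      NO3-N: {bound: upper, high: 10}
      PO4-P: {bound: upper, high: 10}
      Cl2:   {bound: range, low: 0.2, high: 0.5}
      TC:    {bound: upper, high: 10}
      FC:    {bound: upper, high: 2.2}
  S3:
    description: "CPI cycle 1: adds fishery and livestock drinking (FLD)"
    objectives:
      TDS:   {bound: upper, high: 1500}
      TSS:   {bound: upper, high: 5}
      pH:    {bound: range, low: 6.5, high: 8.5}
      BOD5:  {bound: upper, high: 5}
      COD:   {bound: upper, high: 40}
      NH3-N: {bound: upper, high: 0.9}
      NO3-N: {bound: upper, high: 10}
      PO4-P: {bound: upper, high: 2}
      Cl2:   {bound: range, low: 0.2, high: 0.5}
      TC:    {bound: upper, high: 2.2}
      FC:    {bound: absent}
  S4:
    description: "CPI cycle 2: adds recreation uses (FR)"
    objectives:
      TDS:   {bound: upper, high: 450}
      TSS:   {bound: upper, high: 5}
      pH:    {bound: range, low: 6.5, high: 8.0}
      BOD5:  {bound: upper, high: 3}
      COD:   {bound: upper, high: 25}
      NH3-N: {bound: upper, high: 0.3}
      NO3-N: {bound: upper, high: 7}
      PO4-P: {bound: upper, high: 2}
      Cl2:   {bound: range, low: 0.2, high: 0.5}
      TC:    {bound: upper, high: 2.2}
      FC:    {bound: absent}
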