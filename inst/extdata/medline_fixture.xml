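<?xml version="1.0" encoding="UTF-8"?>
<MedlineCitationSet>
  <MedlineCitation>
    <PMID>123</PMID>
    <Article>
      <ArticleTitle>T</ArticleTitle>
      <Abstract>
        <AbstractText>A.</AbstractText>
      </Abstract>
    </Article>
  </MedlineCitation>
  <MedlineCitation>
    <PMID>456</PMID>
    <Article>
      <ArticleTitle>Hepatic lipase and cholesterol.</ArticleTitle>
      <Abstract>
        <AbstractText>Hepatic lipase modulates cholesterol levels. E. coli was not involved. Binding of p53 to MDM2 increases.</AbstractText>
      </Abstract>
    </Article>
  </MedlineCitation>
  <MedlineCitation>
    <PMID>789</PMID>
    <Article>
      <ArticleTitle>No abstract here</ArticleTitle>
    </Article>
  </MedlineCitation>
</MedlineCitationSet>
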