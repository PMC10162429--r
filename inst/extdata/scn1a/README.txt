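SCN1A evidence catalogue fixture.

Files whose values are transcribed from published summary numbers:
  tss.tsv (printed TSS positions; unplaced records carry NA positions),
  constructs.tsv (construct lengths and anchor UEs),
  promoters_revised.bed (revised promoter annotation P1a*/P1b*/P1c*),
  activity_summaries.tsv (printed per-group mean TPM values; SE/n kept NA
  where not printed).

Files suffixed *_synthetic* are synthetic stand-ins: the underlying public
resources (GENCODE transcript exon structure, ENCODE cCRE PLS, PsychENCODE /
FANTOM5 / ENCODE / cell-type-specific / mouse-lifted enhancer calls) publish
genome-wide tracks that are not redistributed here, and the catalogue's
summary numbers do not print these coordinates. The stand-ins are built to
be consistent with every transcribed fact: each printed TSS position falls
inside its untranslated exon, each untranslated exon falls inside its
revised promoter span, the seven "near" GRN enhancer calls sit ~250 kb and
the two "far" calls >700 kb from the CDS span, and the per-source call sets
reproduce the reported corroboration pattern (near region supported by all
six sources, far region by four). They are substitutable: regenerate any of
them from the real resources and the loader will pick them up unchanged.

TSS:166128050 is recorded with discordant=TRUE: its published group label
(h1a/P1a*-associated) conflicts with its printed coordinate, which falls in
the P1b* span. The record is stored verbatim, unresolved.

No interaction loops ship with this fixture (no loop coordinates are
printed); the loops slot loads empty.
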