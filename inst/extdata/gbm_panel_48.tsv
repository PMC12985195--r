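mirna_id	role	brain_enriched
miR-7-5p	tumor_suppressor	+
miR-10b-5p	oncomiR	+
miR-16-5p	tumor_suppressor	+
miR-17-5p	context_dependent	+
miR-18a-5p	oncomiR	-
miR-19b-3p	oncomiR	+
miR-20a-5p	oncomiR	+
miR-21-5p	oncomiR	+
miR-26a-5p	oncomiR	+
miR-29a-3p	context_dependent	+
miR-29b-3p	tumor_suppressor	+
miR-29c-3p	tumor_suppressor	+
miR-30b-5p	context_dependent	+
miR-32-5p	context_dependent	-
miR-34a-5p	tumor_suppressor	-
miR-92a-3p	oncomiR	+
miR-93-5p	context_dependent	-
miR-99a-5p	tumor_suppressor	+
miR-100-5p	tumor_suppressor	+
miR-101-3p	tumor_suppressor	+
miR-103a-3p	tumor_suppressor	+
miR-107-3p	tumor_suppressor	+
miR-125b-5p	oncomiR	+
miR-128-3p	tumor_suppressor	+
miR-136-5p	tumor_suppressor	+
miR-146a-5p	tumor_suppressor	+
miR-146b-5p	tumor_suppressor	-
miR-148a-3p	context_dependent	+
miR-155-5p	oncomiR	-
miR-181a-5p	tumor_suppressor	+
miR-181b-5p	tumor_suppressor	+
miR-181c-5p	tumor_suppressor	+
miR-182-5p	oncomiR	+
miR-204-5p	tumor_suppressor	+
miR-210-3p	oncomiR	+
miR-221-3p	oncomiR	+
miR-222-3p	oncomiR	+
miR-335-5p	oncomiR	+
miR-338-3p	tumor_suppressor	+
miR-340-5p	tumor_suppressor	+
miR-342-3p	tumor_suppressor	+
miR-363-3p	oncomiR	-
miR-370-3p	tumor_suppressor	+
miR-376a-3p	tumor_suppressor	+
miR-410-3p	tumor_suppressor	+
miR-424-5p	tumor_suppressor	+
miR-451a-5p	context_dependent	+
miR-582-5p	oncomiR	-
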