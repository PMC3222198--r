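# Previously published diagnosis filters, named FirstAuthor-Year[-Variant].
# Fill in one filter per line:  name<TAB>query<TAB>provenance
# e.g.  Author-2004-Sensitive<TAB>...query string...<TAB>citation
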