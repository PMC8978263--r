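# libhdf5 from the same prefix R is installed in (conda-style layout:
# $(R_HOME) = <prefix>/lib/R). Falls back to default search paths at link time.
PKG_CPPFLAGS = -I$(R_HOME)/../../include
PKG_LIBS = -L$(R_HOME)/../../lib -lhdf5
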