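# element-wise kernels (batch-norm, ELU, pooling, dropout masks) benefit
# from AVX2/FMA vectorisation; x86-64-v3 is available on any recent x86 CPU
PKG_CXXFLAGS = -O3 -march=x86-64-v3 -funroll-loops
PKG_LIBS = $(LAPACK_LIBS) $(BLAS_LIBS) $(FLIBS)
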