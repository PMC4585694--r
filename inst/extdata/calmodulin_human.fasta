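>CALM_HUMAN mature human calmodulin (148 aa)
ADQLTEEQIAEFKEAFSLFDKDGDGTITTKELGTVMRSLGQNPTEAELQDMINEVDADGN
GTIDFPEFLTMMARKMKDTDSEEEIREAFRVFDKDGNGYISAAELRHVMTNLGEKLTDEE
VDEMIREADIDGDGQVNYEEFVQMMTAK
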