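toluene
  nmrcase

  7  7  0  0  0  0  0  0  0  0999 V2000
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  2  0
  1  6  1  0
  1  7  1  0
  2  3  1  0
  3  4  2  0
  4  5  1  0
  5  6  2  0
M  END
> <C13_ASSIGNMENT>
1:137.8000
2:129.3000
3:128.5000
4:125.6000
5:128.5000
6:129.3000
7:21.4000

> <C13_SHIFTS>
137.8000 129.3000 128.5000 125.6000 128.5000 129.3000 21.4000

$$$$
pyridine
  nmrcase

  6  6  0  0  0  0  0  0  0  0999 V2000
    0.0000    0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  2  0
  1  6  1  0
  2  3  1  0
  3  4  2  0
  4  5  1  0
  5  6  2  0
M  END
> <C13_ASSIGNMENT>
2:149.9000
3:123.8000
4:136.0000
5:123.8000
6:149.9000

> <C13_SHIFTS>
149.9000 123.8000 136.0000 123.8000 149.9000

$$$$
phenol
  nmrcase

  7  7  0  0  0  0  0  0  0  0999 V2000
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  2  0
  1  6  1  0
  1  7  1  0
  2  3  1  0
  3  4  2  0
  4  5  1  0
  5  6  2  0
M  END
> <C13_ASSIGNMENT>
1:155.4000
2:115.7000
3:130.1000
4:121.1000
5:130.1000
6:115.7000

> <C13_SHIFTS>
155.4000 115.7000 130.1000 121.1000 130.1000 115.7000

$$$$
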