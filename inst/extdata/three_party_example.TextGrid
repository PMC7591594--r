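File type = "ooTextFile"
Object class = "TextGrid"

xmin = 0
xmax = 10
tiers? <exists>
size = 3
item []:
    item [1]:
        class = "IntervalTier"
        name = "S1"
        xmin = 0
        xmax = 10
        intervals: size = 4
        intervals [1]:
            xmin = 0
            xmax = 2.5
            text = "one"
        intervals [2]:
            xmin = 2.5
            xmax = 5
            text = ""
        intervals [3]:
            xmin = 5
            xmax = 8
            text = "two"
        intervals [4]:
            xmin = 8
            xmax = 10
            text = ""
    item [2]:
        class = "IntervalTier"
        name = "S2"
        xmin = 0
        xmax = 10
        intervals: size = 5
        intervals [1]:
            xmin = 0
            xmax = 2.75
            text = ""
        intervals [2]:
            xmin = 2.75
            xmax = 4.5
            text = "yes"
        intervals [3]:
            xmin = 4.5
            xmax = 8.1
            text = ""
        intervals [4]:
            xmin = 8.1
            xmax = 9.5
            text = "ok"
        intervals [5]:
            xmin = 9.5
            xmax = 10
            text = ""
    item [3]:
        class = "IntervalTier"
        name = "S3"
        xmin = 0
        xmax = 10
        intervals: size = 3
        intervals [1]:
            xmin = 0
            xmax = 4.6
            text = ""
        intervals [2]:
            xmin = 4.6
            xmax = 5.2
            text = "mm"
        intervals [3]:
            xmin = 5.2
            xmax = 10
            text = ""
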